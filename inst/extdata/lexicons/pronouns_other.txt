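# category: pronoun_other | match: surface
he
she
it
they
we
you
him
her
them
us
his
hers
theirs
yours
ours
its
himself
herself
themselves
yourself
yourselves
ourselves
itself
who
whom
someone
anyone
everyone
nobody
somebody
anybody
everybody
something
anything
nothing
everything
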