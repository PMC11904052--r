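# category: determiner | match: surface
some
any
no
every
each
all
both
few
many
much
more
most
other
another
such
what
which
whose
several
this
these
those
own
one
two
three
four
five
six
seven
eight
nine
ten
first
second
third
last
next
half
whatever
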