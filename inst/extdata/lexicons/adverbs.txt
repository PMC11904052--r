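# category: adverb | match: surface
not
n't
never
again
so
very
too
also
just
now
then
here
there
always
often
really
quite
still
even
only
soon
away
far
maybe
perhaps
almost
already
suddenly
slowly
quickly
terribly
extremely
completely
finally
together
everywhere
somewhere
anywhere
nowhere
instead
later
today
tomorrow
yesterday
once
twice
seldom
rarely
usually
sometimes
ever
else
enough
badly
truly
indeed
anyway
forever
ahead
back
rather
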