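# category: preposition | match: surface
about
of
in
on
at
with
from
for
by
over
under
into
through
after
before
between
against
during
without
around
near
off
out
above
below
across
behind
beyond
toward
towards
upon
within
onto
inside
outside
despite
except
until
since
per
via
among
along
beside
besides
underneath
throughout
to
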