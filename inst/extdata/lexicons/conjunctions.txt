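# category: conjunction | match: surface
and
but
or
because
although
though
while
when
where
how
why
as
than
whether
unless
nor
yet
that
whereas
if
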