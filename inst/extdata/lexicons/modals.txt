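# category: modal | match: surface
will
would
can
could
shall
should
may
might
must
ought
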