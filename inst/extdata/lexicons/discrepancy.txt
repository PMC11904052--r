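# category: discrepancy | match: surface
would
could
should
ought
must
need
needs
needed
want
wants
wanted
wish
wishes
wished
hope
hopes
hoped
if
rather
lack
lacks
lacked
prefer
prefers
preferred
wanna
gotta
hopefully
ideally
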