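# category: interjection | match: surface
oh
wow
yes
yeah
okay
ok
hmm
ugh
oops
ouch
hey
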