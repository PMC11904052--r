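# category: sv | match: lemma
be
have
feel
hate
like
love
think
know
believe
fear
miss
remember
forget
understand
hope
wish
care
admire
adore
appreciate
desire
doubt
dream
enjoy
envy
regret
respect
trust
worry
matter
seem
appear
notice
realize
suppose
prefer
need
expect
mean
wonder
imagine
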