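# category: dav | match: lemma
walk
run
jump
kick
kiss
call
push
pull
throw
catch
grab
climb
drive
eat
drink
sit
stand
fall
carry
hold
touch
shout
cry
smile
laugh
dance
sing
wash
cook
write
stop
go
come
look
watch
talk
speak
scream
stare
turn
move
shake
wave
knock
bite
burn
cover
draw
fight
fly
swim
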