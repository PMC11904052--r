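# category: adjective | match: surface
huge
terrible
charming
happy
sad
angry
afraid
awful
bad
good
big
small
beautiful
ugly
dark
bright
hot
cold
new
old
young
great
horrible
nice
poor
rich
strong
weak
tired
sick
healthy
dangerous
safe
dirty
violent
gentle
quiet
loud
deep
empty
full
heavy
short
tall
wide
narrow
soft
fast
slow
red
blue
green
black
white
colorful
disgusting
awesome
amazing
anxious
nervous
scary
creepy
peaceful
calm
lonely
painful
serious
strange
sudden
wild
intense
graphic
upset
naked
sacred
wicked
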