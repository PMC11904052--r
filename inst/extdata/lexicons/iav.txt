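# category: iav | match: lemma
want
see
scare
help
cheat
imitate
avoid
attack
protect
encourage
comfort
support
tease
bother
hurt
harm
praise
blame
threaten
surprise
annoy
frighten
save
ignore
destroy
injure
rescue
visit
share
promise
warn
tell
ask
answer
explain
describe
use
make
take
get
give
show
try
change
start
finish
play
create
manage
succeed
fail
win
lose
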