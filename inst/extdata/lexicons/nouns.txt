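# category: noun | match: surface
man
men
woman
women
child
children
dog
cat
spider
bug
snake
car
fire
house
tree
water
sky
city
street
room
door
picture
image
person
people
family
friend
doctor
hospital
blood
knife
gun
war
soldier
accident
storm
night
day
world
life
death
animal
bird
flower
garden
mountain
river
ocean
beach
table
chair
window
wall
floor
food
bread
fruit
pencil
book
paper
letter
phone
computer
money
school
teacher
student
problem
thing
place
year
moment
situation
scene
danger
victim
disaster
athlete
emergency
neighborhood
explosion
violence
tragedy
darkness
stranger
creature
weapon
vehicle
forest
kitchen
bedroom
hallway
ceiling
village
station
airport
journey
morning
evening
weekend
monster
shadow
crowd
army
officer
nurse
patient
prisoner
criminal
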