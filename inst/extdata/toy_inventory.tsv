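synset_id	pos	lemmas	hypernyms	gloss
entity.n.01	n	entity	-	that which is perceived to exist
object.n.01	n	object	entity.n.01	a tangible and visible entity
living_thing.n.01	n	living_thing	object.n.01	a living organism
animal.n.01	n	animal,beast	living_thing.n.01	a living organism that feeds on organic matter
dog.n.01	n	dog,hound	animal.n.01	a domesticated animal kept by people as a pet or to guard or hunt
cat.n.01	n	cat	animal.n.01	a small domesticated animal with soft fur kept as a pet
mouse.n.01	n	mouse	animal.n.01	a small rodent with a pointed snout and long tail
horse.n.01	n	horse	animal.n.01	a large animal used for riding and for drawing loads
person.n.01	n	person,individual	living_thing.n.01	a human being
man.n.01	n	man	person.n.01	an adult male person
woman.n.01	n	woman	person.n.01	an adult female person
child.n.01	n	child,kid	person.n.01	a young person not yet an adult
neighbor.n.01	n	neighbor	person.n.01	a person who lives near another
wife.n.01	n	wife	person.n.01	a married woman considered in relation to her spouse
husband.n.01	n	husband	person.n.01	a married man considered in relation to his spouse
friend.n.01	n	friend,companion	person.n.01	a person whom one knows well and regards with affection
plant.n.01	n	plant	living_thing.n.01	a living organism that grows in soil
tree.n.01	n	tree	plant.n.01	a tall plant with a trunk and branches made of wood
fruit.n.01	n	fruit	plant.n.01	the sweet edible product of a tree or other plant
apple.n.01	n	apple	fruit.n.01	a round fruit with red or green skin and crisp flesh
location.n.01	n	location,place	entity.n.01	a point or extent in space
town.n.01	n	town	location.n.01	a populated place smaller than a city
city.n.01	n	city	location.n.01	a large and densely populated place
home.n.01	n	home,house	location.n.01	the place where a person lives
river.n.01	n	river	location.n.01	a large natural stream of water flowing toward the sea
yard.n.01	n	yard,garden	location.n.01	a piece of ground adjoining a house
artifact.n.01	n	artifact	object.n.01	a man-made object
window.n.01	n	window	artifact.n.01	an opening in a wall to admit light and air
door.n.01	n	door	artifact.n.01	a movable barrier used to close off an entrance
car.n.01	n	car,automobile	artifact.n.01	a motor vehicle with four wheels used to carry people
book.n.01	n	book	artifact.n.01	a written work of pages bound together
bank.n.01	n	bank	artifact.n.01	a financial institution that accepts deposits and lends money
bank.n.02	n	bank	location.n.01	sloping land beside a body of water such as a river
bread.n.01	n	bread,loaf	artifact.n.01	a food made from flour and water baked in an oven
abstraction.n.01	n	abstraction	entity.n.01	a general concept
story.n.01	n	story,tale	abstraction.n.01	an account of events told to entertain or inform
idea.n.01	n	idea,thought	abstraction.n.01	the content of cognition
problem.n.01	n	problem,trouble	abstraction.n.01	a state of difficulty that needs to be resolved
time.n.01	n	time	abstraction.n.01	the continuum of experience in which events pass
health.n.01	n	health	abstraction.n.01	the general condition of body and mind
act.v.01	v	act	-	perform an action
move.v.01	v	move	act.v.01	change location or position
run.v.01	v	run,sprint	move.v.01	move fast by using legs
walk.v.01	v	walk,stroll	move.v.01	use legs to advance at a moderate pace
come.v.01	v	come,arrive	move.v.01	move toward or reach a place
go.v.01	v	go,depart	move.v.01	move away from a place
sit.v.01	v	sit	move.v.01	be seated or take a seat
stand.v.01	v	stand	move.v.01	be upright on the feet
fall.v.01	v	fall,drop	move.v.01	descend under the force of gravity
communicate.v.01	v	communicate	act.v.01	convey information to others
say.v.01	v	say,state	communicate.v.01	express something in words
tell.v.01	v	tell,narrate	communicate.v.01	give an account of events to someone
talk.v.01	v	talk,chat	communicate.v.01	exchange spoken words with someone
ask.v.01	v	ask,inquire	communicate.v.01	put a question to someone
perceive.v.01	v	perceive	act.v.01	become aware of through the senses
see.v.01	v	see	perceive.v.01	perceive with the eyes
watch.v.01	v	watch,observe	perceive.v.01	look at attentively over time
hear.v.01	v	hear,listen	perceive.v.01	perceive sound with the ears
think.v.01	v	think,cognize	act.v.01	use the mind to form ideas
know.v.01	v	know	think.v.01	be aware of a fact or truth
remember.v.01	v	remember,recall	think.v.01	bring a past experience back to mind
feel.v.01	v	feel	act.v.01	experience an emotion
love.v.01	v	love,adore	feel.v.01	have a great affection for
worry.v.01	v	worry,fret	feel.v.01	feel anxious about something
enjoy.v.01	v	enjoy,relish	feel.v.01	take pleasure in something
help.v.01	v	help,assist	act.v.01	give aid to someone
work.v.01	v	work,labor	act.v.01	exert effort to achieve a purpose
eat.v.01	v	eat,consume	act.v.01	take food into the body
happy.a.01	a	happy,glad	-	feeling or showing pleasure
sad.a.01	a	sad,unhappy	-	feeling or showing sorrow
old.a.01	a	old,elderly	-	having lived for a long time
young.a.01	a	young,youthful	-	having lived for a short time
big.a.01	a	big,large	-	of great size
small.a.01	a	small,little	-	of limited size
good.a.01	a	good,fine	-	having desirable qualities
bad.a.01	a	bad,poor	-	having undesirable qualities
sick.a.01	a	sick,ill	-	affected by disease or poor health
lonely.a.01	a	lonely,alone	-	sad from being without company
quietly.r.01	r	quietly,softly	-	with little or no sound
quickly.r.01	r	quickly,fast	-	at a rapid rate
slowly.r.01	r	slowly	-	at a low speed
often.r.01	r	often,frequently	-	many times at short intervals
kindly.r.01	r	kindly,warmly	-	in a kind and friendly manner
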