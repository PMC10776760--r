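word,value
abstraction,5.53
act,4.39
adore,2.39
alone,4.82
animal,3.87
apple,5.21
arrive,4.01
artifact,4.74
ask,4.89
assist,2.86
automobile,5.42
bad,4.55
bank,3.59
beast,3.84
big,2.65
book,3.82
bread,6
car,4.79
cat,4.19
chat,3.17
child,4.96
city,1.94
cognize,4.25
come,3.9
communicate,4.32
companion,4.7
consume,5.4
depart,4.08
dog,4.82
door,4.73
drop,4.74
eat,4.08
elderly,2.92
enjoy,3.2
entity,2.44
fall,4.61
fast,2.28
feel,5.58
fine,3.9
frequently,3.57
fret,4.85
friend,3.71
fruit,5.46
garden,2.62
glad,4.81
go,5.42
good,6.1
happy,5.44
health,4.98
hear,3.08
help,4.99
home,4.99
horse,2.37
hound,3.11
house,3.41
husband,3.99
idea,3.38
ill,5.56
individual,3.79
inquire,3.55
kid,4.56
kindly,3.6
know,2.78
labor,3.48
large,4.19
listen,3.59
little,2.87
living_thing,4.89
loaf,3.14
location,1.73
lonely,4.77
love,4.96
man,4.47
mouse,4.74
move,2.79
narrate,5.23
neighbor,4.65
object,4.64
observe,4.54
often,5.18
old,2.43
perceive,3.96
person,4.14
place,5.3
plant,5.85
poor,3.41
problem,4.77
quickly,3.79
quietly,3.68
recall,3.96
relish,3.78
remember,3.96
river,3.94
run,3.26
sad,3.46
say,4.66
see,4.31
sick,3.4
sit,3.31
slowly,4.59
small,3.11
softly,4.35
sprint,3.77
stand,4.24
state,3.51
story,5
stroll,3.98
tale,3.87
talk,4.39
tell,3.8
think,3.15
thought,4.14
time,3.4
town,4.95
tree,2.48
trouble,4.55
unhappy,4.78
walk,3.27
warmly,4.8
watch,4.02
wife,6.23
window,3.17
woman,1.91
work,5.77
worry,3.92
yard,2.92
young,4.07
youthful,4.45
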