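word,value
abstraction,3.04
act,3.92
adore,2.72
alone,3.61
animal,2.98
apple,3.53
arrive,4.85
artifact,2.83
ask,2.54
assist,3.92
automobile,3.76
bad,3.26
bank,3.94
beast,2.5
big,2.86
book,4.89
bread,4.19
car,4.08
cat,4.89
chat,3.61
child,4.2
city,4.34
cognize,2.59
come,3.47
communicate,5
companion,4.5
consume,2.89
depart,1.14
dog,3.76
door,3.26
drop,2.93
eat,3.73
elderly,4.89
enjoy,3.5
entity,3.5
fall,4.75
fast,3.2
feel,2.99
fine,3.61
frequently,2.12
fret,4.48
friend,5
fruit,3.21
garden,4.24
glad,3.11
go,3.67
good,3.82
happy,4.42
health,4.49
hear,3.63
help,4.07
home,3.2
horse,4.06
hound,3.7
house,4.04
husband,2.97
idea,3.2
ill,4.1
individual,4.3
inquire,3.21
kid,2.96
kindly,3.88
know,3.03
labor,2.66
large,3.94
listen,4.35
little,4.53
living_thing,3.97
loaf,4.51
location,3.89
lonely,5
love,2.05
man,3.5
mouse,3.88
move,2.88
narrate,3.66
neighbor,4.32
object,2.69
observe,2.9
often,3.62
old,4.2
perceive,3.85
person,2.95
place,3.95
plant,3.05
poor,1.31
problem,4.01
quickly,3.82
quietly,4.06
recall,3.92
relish,3.02
remember,4.36
river,2.98
run,4.7
sad,3.61
say,3.44
see,3.52
sick,3.69
sit,3.43
slowly,3.87
small,3.3
softly,3.99
sprint,4.58
stand,4.04
state,3.32
story,3.2
stroll,3.47
tale,3.57
talk,3.45
tell,3.09
think,3.56
thought,2.77
time,3.67
town,4.37
tree,4.59
trouble,4.41
unhappy,2.77
walk,5
warmly,3.05
watch,3.71
wife,2.6
window,3.62
woman,4.88
work,3.64
worry,4.32
yard,3.28
young,3.72
youthful,2.24
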