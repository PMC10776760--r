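word,value
abstraction,5.22
act,4.76
adore,5.83
alone,3.27
animal,4.64
apple,4.48
arrive,5.79
artifact,3.87
ask,1.19
assist,5.91
automobile,4.32
bad,6.09
bank,5.81
beast,6.39
big,6.34
book,4.73
bread,2.99
car,3.78
cat,5.86
chat,5.05
child,4.07
city,2.62
cognize,3.6
come,4.82
communicate,6
companion,5.36
consume,7.05
depart,5.34
dog,5.92
door,4.41
drop,3.83
eat,5.1
elderly,6.65
enjoy,8.8
entity,3.97
fall,6.21
fast,7.49
feel,4.37
fine,5.51
frequently,6.06
fret,6.97
friend,3.16
fruit,3.09
garden,5.2
glad,6.07
go,4.05
good,4.52
happy,6.6
health,7.39
hear,5.67
help,4.84
home,6.07
horse,5.27
hound,6.98
house,5.58
husband,3
idea,2.59
ill,3.7
individual,9
inquire,4.37
kid,4.94
kindly,5.06
know,6.56
labor,4.04
large,3.4
listen,5.3
little,5.58
living_thing,3.98
loaf,8.99
location,4.76
lonely,3.46
love,6.03
man,2.07
mouse,4.45
move,5.13
narrate,4.06
neighbor,7.01
object,4.28
observe,6.7
often,2.73
old,7.06
perceive,1.89
person,5.01
place,5.66
plant,4.02
poor,2.61
problem,5.49
quickly,5.05
quietly,6.09
recall,7.27
relish,3.27
remember,5.72
river,3.28
run,6.94
sad,4.39
say,6.19
see,6.08
sick,3.86
sit,1.94
slowly,4.24
small,6.09
softly,6.22
sprint,6.76
stand,3.35
state,4.63
story,5.82
stroll,3.88
tale,4.02
talk,5.66
tell,4.21
think,5.26
thought,5.17
time,5.89
town,3.93
tree,7.62
trouble,4.36
unhappy,4.38
walk,4.78
warmly,5.07
watch,4.81
wife,4.69
window,4.31
woman,8.49
work,3.74
worry,5.26
yard,4.63
young,5.4
youthful,5.05
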