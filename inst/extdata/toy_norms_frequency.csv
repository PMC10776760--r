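word,value
abstraction,2.06
act,3.89
adore,2.44
alone,2.16
animal,2.33
apple,2.62
arrive,2.77
artifact,0.88
ask,2.19
assist,2.55
automobile,2.23
bad,1.04
bank,2.63
beast,4.68
big,1.86
book,3.79
bread,3.73
car,3.33
cat,2.15
chat,1.84
child,2.75
city,3.63
cognize,3.23
come,5.03
communicate,2.85
companion,2.16
consume,1.17
depart,3.16
dog,1.88
door,2.51
drop,3.33
eat,1.92
elderly,2.61
enjoy,4.58
entity,3.68
fall,2.32
fast,2.62
feel,3.03
fine,3.72
frequently,3.41
fret,3.44
friend,2.79
fruit,2.79
garden,3.24
glad,1.3
go,4.53
good,2.7
happy,3.52
health,4.34
hear,4.96
help,2.37
home,2.9
horse,1.33
hound,3.26
house,2.92
husband,3.52
idea,3.17
ill,1.15
individual,2
inquire,2.05
kid,3.81
kindly,1.53
know,3.82
labor,4.53
large,2.43
listen,2.83
little,4.14
living_thing,1.56
loaf,1.78
location,3.83
lonely,1.14
love,2.1
man,3.79
mouse,3.17
move,3.14
narrate,2.03
neighbor,4.81
object,4.49
observe,3.01
often,1.77
old,1.64
perceive,3.48
person,2.72
place,2.68
plant,2.66
poor,4.49
problem,3.51
quickly,2.69
quietly,0.42
recall,4.29
relish,3.6
remember,3.13
river,3.22
run,2.16
sad,2.89
say,0.9
see,2.91
sick,2.51
sit,1.76
slowly,4.2
small,2.35
softly,4.59
sprint,3.48
stand,2.13
state,3.88
story,5.27
stroll,3.05
tale,3.14
talk,3.82
tell,1.93
think,2.66
thought,2.26
time,2.8
town,3.88
tree,2.72
trouble,1.85
unhappy,2.84
walk,2.84
warmly,1.62
watch,2
wife,1.31
window,2.67
woman,2.19
work,4.23
worry,1.89
yard,3.7
young,3.18
youthful,4.41
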