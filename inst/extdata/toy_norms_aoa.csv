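word,value
abstraction,8.45
act,7.17
adore,5.73
alone,5.47
animal,8.9
apple,9.23
arrive,7.34
artifact,5.68
ask,2.94
assist,3.2
automobile,1.82
bad,7.17
bank,8.08
beast,6.73
big,1.5
book,5.63
bread,3.68
car,7.14
cat,1.98
chat,1.5
child,8.85
city,6.79
cognize,8.61
come,5.47
communicate,6.99
companion,2.14
consume,5.7
depart,7.71
dog,1.5
door,5.73
drop,2.4
eat,5.19
elderly,4.74
enjoy,9.01
entity,4.75
fall,6.97
fast,6.84
feel,4.78
fine,4.57
frequently,7.07
fret,3.82
friend,5.99
fruit,7.24
garden,10.93
glad,3.01
go,6.33
good,6.82
happy,7.67
health,7.6
hear,10.85
help,4.61
home,4.09
horse,4.38
hound,3.43
house,4.3
husband,2.42
idea,8.24
ill,5.4
individual,8.5
inquire,5.92
kid,9.98
kindly,8.15
know,7.35
labor,6.44
large,10.11
listen,5.68
little,1.5
living_thing,7.79
loaf,7.23
location,1.5
lonely,8.83
love,2.98
man,6.74
mouse,6.19
move,6.49
narrate,5.22
neighbor,9.55
object,7.71
observe,3.4
often,6.04
old,2.89
perceive,8.48
person,8.16
place,1.61
plant,6.37
poor,8.78
problem,5.54
quickly,5.36
quietly,5.37
recall,8.04
relish,2.93
remember,4.7
river,4.24
run,7.72
sad,7.37
say,1.5
see,3.09
sick,3.05
sit,5.93
slowly,8.88
small,11.52
softly,7.1
sprint,8.61
stand,6.31
state,2.84
story,6.94
stroll,5.5
tale,8.89
talk,4.6
tell,3.16
think,2.77
thought,8.81
time,4.25
town,5.93
tree,4.44
trouble,1.5
unhappy,10.76
walk,7.32
warmly,5.34
watch,8.27
wife,5.34
window,5.18
woman,2.74
work,5.51
worry,4.22
yard,6.07
young,3.32
youthful,3.27
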