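word	tag
the	DT
a	DT
an	DT
this	DT
that	IN
that	DT
these	DT
those	DT
each	DT
every	DT
either	DT
some	DT
any	DT
no	DT
all	DT
both	DT
few	JJ
many	JJ
much	JJ
several	JJ
such	JJ
another	DT
other	JJ
others	NNS
i	PRP
you	PRP
he	PRP
she	PRP
it	PRP
we	PRP
they	PRP
me	PRP
him	PRP
us	PRP
them	PRP
myself	PRP
yourself	PRP
himself	PRP
herself	PRP
itself	PRP
ourselves	PRP
themselves	PRP
mine	PRP
yours	PRP
hers	PRP
theirs	PRP
ours	PRP
anybody	PRP
anyone	PRP
anything	PRP
everybody	PRP
everyone	PRP
everything	PRP
somebody	PRP
someone	PRP
something	PRP
my	PRP$
your	PRP$
his	PRP$
her	PRP$
her	PRP
its	PRP$
our	PRP$
their	PRP$
who	WP
whom	WP
whose	WP$
which	WDT
when	WRB
where	WRB
why	WRB
how	WRB
in	IN
on	IN
at	IN
by	IN
for	IN
with	IN
about	IN
against	IN
between	IN
into	IN
through	IN
during	IN
before	IN
after	IN
above	IN
below	IN
from	IN
up	IN
down	IN
out	IN
off	IN
over	IN
under	IN
of	IN
despite	IN
because	IN
although	IN
while	IN
since	IN
until	IN
unless	IN
than	IN
as	IN
if	IN
whether	IN
per	IN
via	IN
near	IN
without	IN
within	IN
upon	IN
among	IN
around	IN
to	TO
can	MD
could	MD
will	MD
would	MD
shall	MD
should	MD
may	MD
might	MD
must	MD
and	CC
but	CC
or	CC
so	CC
yet	CC
nor	CC
very	RB
also	RB
just	RB
too	RB
quite	RB
rather	RB
almost	RB
always	RB
often	RB
sometimes	RB
usually	RB
never	RB
again	RB
soon	RB
still	RB
already	RB
even	RB
only	RB
really	RB
perhaps	RB
maybe	RB
away	RB
back	RB
here	RB
there	EX
there	RB
now	RB
then	RB
well	RB
more	RBR
most	RBS
less	RBR
least	RBS
frequently	RB
rarely	RB
politely	RB
kindly	RB
mainly	RB
elsewhere	RB
instead	RB
together	RB
once	RB
twice	RB
not	RB
n't	RB
oh	UH
yes	UH
please	UH
one	CD
two	CD
three	CD
four	CD
five	CD
six	CD
seven	CD
eight	CD
nine	CD
ten	CD
hundred	CD
thousand	CD
be	VB
is	VBZ
are	VBP
was	VBD
were	VBD
am	VBP
been	VBN
being	VBG
have	VBP
have	VB
has	VBZ
had	VBD
do	VBP
do	VB
does	VBZ
did	VBD
done	VBN
go	VB
goes	VBZ
went	VBD
gone	VBN
say	VB
says	VBZ
said	VBD
make	VB
makes	VBZ
made	VBD
take	VB
takes	VBZ
took	VBD
taken	VBN
come	VB
comes	VBZ
came	VBD
see	VB
sees	VBZ
saw	VBD
seen	VBN
get	VB
gets	VBZ
got	VBD
gotten	VBN
give	VB
gives	VBZ
gave	VBD
given	VBN
know	VB
knows	VBZ
knew	VBD
known	VBN
think	VB
thinks	VBZ
thought	VBD
tell	VB
tells	VBZ
told	VBD
feel	VB
feels	VBZ
felt	VBD
leave	VB
leaves	VBZ
leaves	NNS
left	VBD
keep	VB
keeps	VBZ
kept	VBD
run	VB
runs	VBZ
ran	VBD
sit	VB
sits	VBZ
sat	VBD
stand	VB
stands	VBZ
stood	VBD
find	VB
finds	VBZ
found	VBD
hold	VB
holds	VBZ
held	VBD
bring	VB
brings	VBZ
brought	VBD
begin	VB
began	VBD
begun	VBN
write	VB
writes	VBZ
wrote	VBD
written	VBN
speak	VB
speaks	VBZ
spoke	VBD
spoken	VBN
meet	VB
meets	VBZ
met	VBD
pay	VB
pays	VBZ
paid	VBD
lose	VB
loses	VBZ
lost	VBD
mean	VB
means	VBZ
meant	VBD
spend	VB
spends	VBZ
spent	VBD
build	VB
builds	VBZ
built	VBD
send	VB
sends	VBZ
sent	VBD
fall	VB
falls	VBZ
fell	VBD
fallen	VBN
grow	VB
grows	VBZ
grew	VBD
grown	VBN
draw	VB
draws	VBZ
drew	VBD
drawn	VBN
fly	VB
flies	VBZ
flew	VBD
flown	VBN
drive	VB
drives	VBZ
drove	VBD
driven	VBN
eat	VB
eats	VBZ
ate	VBD
eaten	VBN
break	VB
breaks	VBZ
broke	VBD
broken	VBN
choose	VB
chooses	VBZ
chose	VBD
chosen	VBN
buy	VB
buys	VBZ
bought	VBD
catch	VB
catches	VBZ
caught	VBD
teach	VB
teaches	VBZ
taught	VBD
fight	VB
fight	NN
fights	VBZ
fought	VBD
seek	VB
seeks	VBZ
sought	VBD
sleep	VB
sleeps	VBZ
slept	VBD
wake	VB
wakes	VBZ
woke	VBD
woken	VBN
wear	VB
wears	VBZ
wore	VBD
worn	VBN
throw	VB
throws	VBZ
threw	VBD
thrown	VBN
hear	VB
hears	VBZ
heard	VBD
lead	VB
leads	VBZ
led	VBD
become	VB
becomes	VBZ
became	VBD
let	VB
lets	VBZ
put	VB
puts	VBZ
set	VB
sets	VBZ
want	VB
wants	VBZ
need	VB
needs	VBZ
like	VB
like	IN
likes	VBZ
love	VB
loves	VBZ
help	VB
helps	VBZ
try	VB
tries	VBZ
ask	VB
asks	VBZ
work	VB
work	NN
works	VBZ
call	VB
calls	VBZ
use	VB
uses	VBZ
turn	VB
turns	VBZ
start	VB
starts	VBZ
show	VB
shows	VBZ
play	VB
plays	VBZ
move	VB
moves	VBZ
live	VB
lives	VBZ
believe	VB
believes	VBZ
happen	VB
happens	VBZ
watch	VB
watch	NN
watches	VBZ
follow	VB
follows	VBZ
stop	VB
stops	VBZ
create	VB
creates	VBZ
open	VB
open	JJ
opens	VBZ
walk	VB
walks	VBZ
win	VB
wins	VBZ
offer	VB
offers	VBZ
remember	VB
remembers	VBZ
consider	VB
considers	VBZ
appear	VB
appears	VBZ
serve	VB
serves	VBZ
die	VB
dies	VBZ
expect	VB
expects	VBZ
stay	VB
stays	VBZ
reach	VB
reaches	VBZ
remain	VB
remains	VBZ
care	VB
care	NN
cares	VBZ
chat	VB
chats	VBZ
listen	VB
listens	VBZ
decline	VB
declines	VBZ
visit	VB
visits	VBZ
socialize	VB
socializes	VBZ
argue	VB
argues	VBZ
arguing	VBG
prefer	VB
prefers	VBZ
discuss	VB
discusses	VBZ
discussing	VBG
enjoy	VB
enjoys	VBZ
hope	VB
hopes	VBZ
hoping	VBG
look	VB
looks	VBZ
looking	VBG
talk	VB
talks	VBZ
insist	VB
insists	VBZ
amble	VB
ambles	VBZ
venture	VB
ventures	VBZ
worry	VB
worries	VBZ
miss	VB
misses	VBZ
cry	VB
cries	VBZ
smile	VB
smiles	VBZ
laugh	VB
laughs	VBZ
plan	VB
plans	VBZ
learn	VB
learns	VBZ
decide	VB
decides	VBZ
change	VB
changes	VBZ
wish	VB
wishes	VBZ
share	VB
shares	VBZ
thank	VB
thanks	VBZ
agree	VB
agrees	VBZ
arrive	VB
arrives	VBZ
return	VB
returns	VBZ
carry	VB
carries	VBZ
describe	VB
develop	VB
notice	VB
notices	VBZ
receive	VB
receives	VBZ
refuse	VB
refuses	VBZ
seem	VB
seems	VBZ
sell	VB
sells	VBZ
shout	VB
shouts	VBZ
sing	VB
sings	VBZ
suffer	VB
suffers	VBZ
suggest	VB
suggests	VBZ
support	VB
suppose	VB
travel	VB
travels	VBZ
treat	VB
treats	VBZ
trust	VB
trusts	VBZ
understand	VB
understands	VBZ
wait	VB
waits	VBZ
wash	VB
washes	VBZ
wonder	VB
wonders	VBZ
feeling	VBG
feeling	NN
caring	VBG
man	NN
woman	NN
child	NN
person	NN
people	NNS
time	NN
year	NN
day	NN
way	NN
thing	NN
life	NN
hand	NN
part	NN
eye	NN
place	NN
week	NN
case	NN
point	NN
number	NN
group	NN
problem	NN
fact	NN
story	NN
neighbor	NN
neighbors	NNS
wife	NN
husband	NN
grandchild	NN
grandson	NN
town	NN
home	NN
health	NN
issue	NN
yard	NN
politics	NNS
view	NN
views	NNS
window	NN
chance	NN
house	NN
hint	NN
night	NN
morning	NN
friend	NN
family	NN
door	NN
room	NN
water	NN
food	NN
money	NN
school	NN
job	NN
car	NN
city	NN
country	NN
world	NN
war	NN
history	NN
idea	NN
body	NN
book	NN
business	NN
area	NN
word	NN
name	NN
river	NN
bank	NN
dog	NN
cat	NN
tree	NN
fruit	NN
apple	NN
belief	NN
beliefs	NNS
old	JJ
older	JJR
oldest	JJS
good	JJ
new	JJ
first	JJ
last	JJ
long	JJ
great	JJ
little	JJ
own	JJ
big	JJ
high	JJ
different	JJ
small	JJ
large	JJ
next	JJ
early	JJ
young	JJ
younger	JJR
important	JJ
public	JJ
bad	JJ
same	JJ
able	JJ
sick	JJ
ill	JJ
lonely	JJ
happy	JJ
sad	JJ
busy	JJ
political	JJ
nice	JJ
interested	JJ
unwell	JJ
alone	JJ
due	JJ
free	JJ
full	JJ
quiet	JJ
quietly	RB
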