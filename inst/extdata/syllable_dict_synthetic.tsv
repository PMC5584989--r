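make	1
made	1
take	1
came	1
come	1
some	1
time	1
give	1
gave	1
have	1
love	1
live	1
move	1
more	1
store	1
score	1
there	1
where	1
were	1
here	1
ease	1
those	1
these	1
close	1
chose	1
choose	1
house	1
mouse	1
horse	1
nurse	1
purse	1
course	1
source	1
state	1
rate	1
late	1
gate	1
date	1
fate	1
plate	1
plane	1
line	1
nine	1
fine	1
wine	1
mine	1
shine	1
while	1
smile	1
white	1
write	1
quite	1
site	1
size	1
prize	1
rise	1
wise	1
use	1
fuse	1
huge	1
cute	1
tube	1
cube	1
note	1
nose	1
rose	1
bone	1
stone	1
alone	2
phone	1
home	1
hope	1
rope	1
slope	1
scope	1
shape	1
tape	1
cape	1
case	1
base	1
phase	1
phrase	1
place	1
space	1
face	1
race	1
trace	1
grace	1
page	1
cage	1
stage	1
range	1
change	1
strange	1
large	1
charge	1
edge	1
bridge	1
judge	1
knowledge	2
village	2
message	2
image	2
usage	2
average	3
leverage	3
storage	2
service	2
practice	2
notice	2
office	2
voice	1
choice	1
juice	1
piece	1
peace	1
force	1
since	1
once	1
dance	1
chance	1
france	1
science	2
patience	2
sentence	2
evidence	3
difference	3
experience	4
sequence	2
influence	3
absence	2
presence	2
distance	2
instance	2
substance	2
balance	2
surface	2
purpose	2
promise	2
purchase	2
disease	2
increase	2
decrease	2
release	2
because	2
clause	1
pause	1
cause	1
value	2
issue	2
tissue	2
statue	2
argue	2
rescue	2
venue	2
continue	3
pursue	2
due	1
blue	1
true	1
clue	1
glue	1
sue	1
cue	1
queue	1
table	2
able	2
cable	2
stable	2
little	2
middle	2
simple	2
sample	2
example	3
people	2
purple	2
circle	2
uncle	2
ankle	2
angle	2
single	2
couple	2
trouble	2
double	2
bubble	2
bottle	2
battle	2
gentle	2
title	2
whole	1
scale	1
style	1
cycle	2
mile	1
file	1
rule	1
role	1
pole	1
hole	1
mole	1
male	1
female	2
tale	1
sale	1
life	1
wife	1
knife	1
five	1
drive	1
leave	1
sleeve	1
serve	1
curve	1
nerve	1
twelve	1
solve	1
involve	2
observe	2
reserve	2
deserve	2
achieve	2
believe	2
receive	2
relieve	2
perceive	2
wave	1
save	1
brave	1
grave	1
slave	1
cave	1
active	2
native	2
motive	2
relative	3
negative	3
positive	3
sensitive	3
massive	2
passive	2
extensive	3
expensive	3
effective	3
objective	3
subjective	3
perspective	3
alternative	4
narrative	3
initiative	4
executive	4
creative	3
primitive	3
definite	3
opposite	3
favorite	3
minute	2
appropriate	4
separate	3
moderate	3
delicate	3
accurate	3
adequate	3
ultimate	3
intimate	3
climate	2
estimate	3
candidate	3
fortunate	3
immediate	4
deliberate	4
elaborate	4
approximate	4
graduate	3
chocolate	2
template	2
pirate	2
private	2
senate	2
palate	2
rhythm	2
myth	1
gym	1
hymn	1
lynx	1
crypt	1
cyst	1
lymph	1
nymph	1
sync	1
tryst	1
myrrh	1
dryly	2
shyly	2
slyly	2
asked	1
walked	1
talked	1
helped	1
jumped	1
looked	1
worked	1
turned	1
learned	1
played	1
stayed	1
showed	1
followed	2
borrowed	2
called	1
filled	1
killed	1
pulled	1
rolled	1
smiled	1
lived	1
loved	1
moved	1
used	1
caused	1
raised	1
praised	1
closed	1
increased	2
decreased	2
released	2
based	1
placed	1
faced	1
forced	1
produced	2
reduced	2
induced	2
introduced	3
changed	1
charged	1
managed	2
arranged	2
engaged	2
damaged	2
described	2
observed	2
involved	2
improved	2
proved	1
approved	2
removed	2
received	2
believed	2
achieved	2
served	1
preserved	2
measured	2
featured	2
captured	2
structured	2
required	2
desired	2
tired	1
fired	1
hired	1
compared	2
prepared	2
shared	1
cared	1
declared	2
stored	1
scored	1
explored	2
ignored	2
bored	1
considered	3
delivered	3
discovered	3
remembered	3
offered	2
ordered	2
gathered	2
covered	2
answered	2
fire	1,2
hour	1,2
our	1,2
flower	1,2
power	1,2
towel	1,2
royal	1,2
loyal	1,2
poem	1,2
quiet	1,2
diet	1,2
real	1,2
idea	2,3
area	2,3
being	1,2
seeing	1,2
doing	1,2
going	1,2
ion	1,2
lion	1,2
prior	1,2
via	1,2
trial	1,2
dial	1,2
liable	2,3
variable	3,4
create	1,2
naturally	3,4
generally	3,4
literally	3,4
actually	3,4
usually	3,4
especially	3,4
basically	3,4
every	2,3
family	2,3
memory	2,3
different	2,3
interest	2,3
interesting	3,4
favorable	3,4
laboratory	4,5
temperature	3,4
literature	3,4
miniature	3,4
one	1
two	1
who	1
whose	1
do	1
to	1
shoe	1
toe	1
eye	1
aye	1
dye	1
bye	1
ocean	2
the	1
a	1
i	1
orange	2
everyone	3
everything	3
anyone	3
something	2
somewhere	2
business	2
wednesday	2
february	4
vegetable	4
comfortable	4
colleague	2
league	1
tongue	1
fatigue	2
technique	2
unique	2
antique	2
physique	2
plague	1
vague	1
morgue	1
catalogue	3
dialogue	3
analogue	3
heart	1
learn	1
earth	1
early	2
heard	1
search	1
research	2
beauty	2
beautiful	3
bureau	2
plateau	2
gauge	1
aisle	1
isle	1
island	2
iron	2
quiz	1
squirrel	2
jewel	2
cruel	2
fuel	2
duel	2
gruel	2
vowel	2
bowel	2
novel	2
level	2
model	2
label	2
camel	2
channel	2
panel	2
barrel	2
quarrel	2
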