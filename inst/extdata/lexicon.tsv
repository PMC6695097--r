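the	function	the
a	function	a
an	function	an
his	function	his
her	function	her
their	function	their
its	function	its
my	function	my
your	function	your
our	function	our
to	function	to
of	function	of
in	function	in
on	function	on
at	function	at
with	function	with
for	function	for
and	function	and
but	function	but
or	function	or
some	function	some
any	function	any
this	function	this
that	function	that
these	function	these
those	function	those
he	function	he
she	function	she
it	function	it
they	function	they
we	function	we
you	function	you
i	function	i
him	function	him
them	function	them
us	function	us
there	function	there
here	function	here
had	function	had
has	function	has
have	function	have
do	function	do
does	function	does
did	function	did
not	function	not
no	function	no
can	function	can
could	function	could
will	function	will
would	function	would
from	function	from
by	function	by
up	function	up
down	function	down
out	function	out
over	function	over
into	function	into
as	function	as
if	function	if
so	function	so
then	function	then
when	function	when
while	function	while
be	be_form	be
am	be_form	be
is	be_form	be
are	be_form	be
was	be_form	be
were	be_form	be
been	be_form	be
being	be_form	be
bucket	content	bucket
buckets	content	bucket
daughter	content	daughter
daughters	content	daughter
table	content	table
tables	content	table
farmer	content	farmer
farmers	content	farmer
garden	content	garden
gardens	content	garden
window	content	window
windows	content	window
letter	content	letter
letters	content	letter
dinner	content	dinner
dinners	content	dinner
wagon	content	wagon
wagons	content	wagon
sister	content	sister
sisters	content	sister
brother	content	brother
brothers	content	brother
ticket	content	ticket
tickets	content	ticket
jacket	content	jacket
jackets	content	jacket
kitchen	content	kitchen
kitchens	content	kitchen
orange	content	orange
oranges	content	orange
leg	content	leg
legs	content	leg
boy	content	boy
boys	content	boy
dog	content	dog
dogs	content	dog
cat	content	cat
cats	content	cat
tree	content	tree
trees	content	tree
school	content	school
schools	content	school
father	content	father
fathers	content	father
cloud	content	cloud
clouds	content	cloud
boat	content	boat
boats	content	boat
song	content	song
songs	content	song
puppy	content	puppy
puppies	content	puppy
man	content	man
men	content	man
water	content	water
bread	content	bread
faucet	content	faucet
dessert	content	dessert
apple	content	apple
pie	content	pie
ocean	content	ocean
pirate	content	pirate
thunder	content	thunder
guitar	content	guitar
piano	content	piano
doctor	content	doctor
nurse	content	nurse
mountain	content	mountain
river	content	river
hold	content	hold
holds	content	hold
held	content	hold
set	content	set
sets	content	set
turn	content	turn
turns	content	turn
turned	content	turn
turning	content	turn
carry	content	carry
carries	content	carry
carried	content	carry
clean	content	clean
cleans	content	clean
cleaned	content	clean
find	content	find
finds	content	find
found	content	find
drop	content	drop
drops	content	drop
dropped	content	drop
wash	content	wash
washes	content	wash
washed	content	wash
open	content	open
opens	content	open
opened	content	open
close	content	close
closes	content	close
closed	content	close
paint	content	paint
paints	content	paint
painted	content	paint
break	content	break
breaks	content	break
broke	content	break
broken	content	break
hurry	content	hurry
hurries	content	hurry
hurried	content	hurry
forget	content	forget
forgets	content	forget
forgot	content	forget
see	content	see
sees	content	see
saw	content	see
seen	content	see
hear	content	hear
hears	content	hear
heard	content	hear
go	content	go
goes	content	go
went	content	go
gone	content	go
going	content	go
sit	content	sit
sits	content	sit
sat	content	sit
fall	content	fall
falls	content	fall
fell	content	fall
sail	content	sail
sails	content	sail
sailed	content	sail
sing	content	sing
sings	content	sing
sang	content	sing
dance	content	dance
dances	content	dance
danced	content	dance
climb	content	climb
climbs	content	climb
climbed	content	climb
cook	content	cook
cooks	content	cook
cooked	content	cook
ride	content	ride
rides	content	ride
rode	content	ride
swim	content	swim
swims	content	swim
swam	content	swim
play	content	play
plays	content	play
played	content	play
big	content	big
small	content	small
red	content	red
green	content	green
old	content	old
new	content	new
little	content	little
heavy	content	heavy
fast	content	fast
slow	content	slow
very	content	very
quickly	content	quickly
hot	content	hot
cold	content	cold
happy	content	happy
loud	content	loud
purple	content	purple
gentle	content	gentle
unicorn	content	unicorn
dragon	content	dragon
wizard	content	wizard
comet	content	comet
volcano	content	volcano
jungle	content	jungle
robot	content	robot
castle	content	castle
galaxy	content	galaxy
meteor	content	meteor
goblin	content	goblin
lantern	content	lantern
marble	content	marble
anchor	content	anchor
turnip	content	turnip
walrus	content	walrus
zebra	content	zebra
igloo	content	igloo
kayak	content	kayak
pebble	content	pebble
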