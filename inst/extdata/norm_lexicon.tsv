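tmrw	tomorrow
2day	today
2moro	tomorrow
2morrow	tomorrow
2nite	tonight
4eva	forever
4ever	forever
gdn8	good night
gn8	good night
lemme	let me
wknd	weekend
comee	come
gr8	great
b4	before
thx	thanks
thnx	thanks
pls	please
plz	please
luv	love
ppl	people
msg	message
nite	night
cuz	because
coz	because
bcoz	because
gonna	going to
wanna	want to
gotta	got to
dunno	do not know
kinda	kind of
sorta	sort of
outta	out of
lotta	lot of
ya	you
yall	you all
im	i am
ive	i have
dont	do not
cant	can not
wont	will not
didnt	did not
doesnt	does not
isnt	is not
wasnt	was not
couldnt	could not
shouldnt	should not
wouldnt	would not
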