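# Curated subset of the published VADER valence ratings (MIT licence),
# word <TAB> mean valence on [-4, 4]. Reduced lexicon: texts whose sentiment
# words fall outside this subset will score closer to neutral than they would
# under the full ~7.5k-entry lexicon.
abandon	-1.9
abandoned	-2.0
abuse	-3.2
admire	2.2
adore	2.9
afraid	-2.2
aggressive	-1.2
agony	-3.3
agree	1.5
alarm	-1.4
alive	1.6
alone	-1.0
amazing	2.8
anger	-2.7
angry	-2.3
anxiety	-2.0
anxious	-1.9
apathy	-1.2
appreciate	1.9
assault	-2.9
attack	-2.1
awesome	3.1
awful	-2.0
bad	-2.5
battle	-1.6
beautiful	2.9
benefit	1.7
best	3.2
betray	-3.0
better	1.9
bless	1.8
blessed	2.9
bomb	-2.4
bore	-1.4
bored	-1.2
boring	-1.3
brave	2.4
brilliant	2.8
broke	-1.6
broken	-2.0
calm	1.3
cancer	-3.4
care	2.2
careful	1.2
careless	-1.5
casualty	-2.4
celebrate	2.7
champion	2.4
chaos	-2.1
charm	1.8
cheat	-2.4
cheer	2.3
cheerful	2.5
clean	1.7
clever	2.0
collapse	-1.6
comfort	1.5
confident	2.2
conflict	-1.7
confused	-1.2
congratulations	2.9
contagion	-1.8
courage	2.2
coward	-2.0
crash	-1.7
crazy	-1.4
crime	-2.5
crisis	-3.1
cruel	-2.8
cry	-2.0
cure	2.1
curse	-2.2
cut	-1.1
cute	2.0
damage	-2.2
danger	-2.4
dangerous	-2.2
dead	-3.3
deadly	-2.9
death	-2.9
defeat	-1.7
depressed	-2.6
depression	-2.7
desperate	-2.0
destroy	-2.4
destruction	-2.6
devastate	-3.0
devastating	-3.0
die	-2.9
died	-2.6
dirty	-1.7
disappointed	-2.1
disaster	-3.1
disease	-2.0
distress	-2.4
doom	-2.4
doubt	-1.4
dread	-2.5
dying	-2.9
eager	1.7
easy	1.6
efficient	1.5
embarrassed	-1.7
emergency	-2.2
encourage	2.0
enemy	-2.3
energetic	1.9
enjoy	2.2
enthusiastic	2.5
evil	-3.4
excellent	2.7
excited	2.7
exciting	2.6
exhausted	-1.9
fail	-2.3
failed	-2.3
failure	-2.6
fair	1.4
faith	2.0
fake	-1.9
fantastic	2.6
fatal	-2.8
fatality	-2.9
favorite	2.0
fear	-2.2
fearful	-2.4
fight	-1.6
fine	0.8
fired	-2.4
foolish	-1.8
forgive	1.5
fortunate	2.1
fraud	-2.8
free	2.3
freedom	2.3
fresh	1.3
friend	2.2
friendly	2.2
frightened	-2.2
frustrated	-2.4
fun	2.3
funny	1.9
generous	2.3
gentle	1.9
gift	1.9
glad	2.0
gloom	-2.1
good	1.9
grace	1.9
grateful	2.4
great	3.1
greed	-2.4
grief	-2.7
grim	-2.0
happy	2.7
harm	-2.4
harmful	-2.5
hate	-2.7
hatred	-3.2
heal	2.0
healthy	2.1
heartbroken	-3.1
hell	-3.6
help	1.7
helpful	1.8
helpless	-2.0
hero	2.6
honest	2.3
honor	2.4
hope	1.9
hopeful	2.3
hopeless	-2.6
horrible	-2.5
horror	-2.8
hostile	-2.2
humiliate	-2.7
hunger	-2.0
hurt	-2.4
ideal	2.2
idiot	-2.3
ignorant	-1.9
ill	-1.8
illness	-2.1
important	1.2
impressive	2.2
improve	1.9
improvement	1.9
infect	-2.0
infected	-2.2
infection	-2.1
innocent	1.6
insane	-1.7
inspire	2.3
inspiring	2.6
insult	-2.3
intelligent	2.3
interesting	1.7
jeopardy	-2.2
jobless	-2.2
joke	1.0
joy	2.8
joyful	2.9
kill	-3.7
killed	-3.4
killing	-3.4
kind	2.4
kiss	1.8
laugh	2.2
laughing	2.6
lazy	-1.4
limited	-1.1
lol	2.4
lonely	-2.2
lose	-1.7
loser	-2.4
loss	-1.3
lost	-1.3
love	3.2
loved	2.9
lovely	2.8
loving	2.9
loyal	2.3
luck	2.0
lucky	2.4
mad	-2.2
merry	2.4
mess	-1.5
miracle	2.8
miserable	-2.7
misery	-2.9
miss	-1.0
missing	-1.3
mistake	-1.7
mock	-1.8
murder	-3.5
nasty	-2.6
negative	-2.7
nervous	-1.8
nice	1.8
no	-1.2
noble	2.1
numb	-1.4
offend	-2.2
ok	1.2
okay	1.2
opportunity	1.8
optimistic	2.4
outbreak	-1.9
pain	-2.5
painful	-2.6
panic	-2.4
paradise	3.2
peace	2.5
peaceful	2.4
perfect	2.7
play	1.5
pleasant	2.3
please	1.3
pleasure	2.6
poison	-2.8
poor	-1.9
positive	2.6
poverty	-2.5
praise	2.4
pray	1.8
precious	2.6
pretty	2.2
problem	-1.7
progress	1.8
promise	1.4
protect	1.7
proud	2.6
punish	-2.4
quarantine	-1.4
rage	-2.9
recession	-1.6
recover	1.7
recovery	1.9
regret	-2.0
reject	-1.9
relief	1.9
relieved	2.0
rescue	2.0
resilient	2.0
rich	2.0
risk	-1.1
romantic	2.5
ruin	-2.4
sad	-2.1
sadly	-2.1
safe	1.8
safety	1.8
satisfied	2.0
save	2.2
scam	-2.6
scandal	-2.2
scare	-2.2
scared	-2.2
scary	-2.2
secure	1.5
selfish	-2.1
severe	-1.8
shame	-2.1
share	1.2
shock	-1.9
shortage	-1.6
sick	-2.3
smart	1.7
smile	2.0
solution	1.4
sorrow	-2.5
sorry	-0.3
special	1.7
splendid	2.9
steal	-2.6
stress	-2.0
stressed	-2.2
strong	2.3
struggle	-2.0
stupid	-2.4
succeed	2.2
success	2.7
successful	2.7
suffer	-2.5
suffering	-2.6
suicide	-3.5
super	2.9
support	1.7
sweet	2.0
sympathy	1.5
terrible	-2.1
terror	-3.1
thank	1.5
thankful	2.7
thanks	1.9
threat	-2.2
thrilled	3.0
tired	-1.4
tough	-1.1
toxic	-2.5
tragedy	-3.1
tragic	-2.9
trust	2.3
ugly	-2.2
unemployed	-2.1
unemployment	-2.3
unfair	-2.3
unfortunate	-1.9
unhappy	-2.4
unsafe	-2.0
upset	-1.9
useless	-1.9
victim	-1.9
victory	2.7
violence	-3.1
violent	-2.9
virus	-1.8
vulnerable	-1.2
war	-2.9
warm	1.6
warning	-1.4
waste	-1.8
weak	-1.9
wealth	2.2
welcome	2.0
well	1.1
win	2.8
winner	2.8
winning	2.4
wise	2.2
wonderful	2.7
worry	-1.9
worried	-1.7
worse	-2.1
worst	-3.1
worth	1.7
wow	2.8
wrong	-2.1
yeah	1.2
yes	1.7
handsome	2.2
:)	1.3
:-)	1.3
:(	-1.9
:-(	-1.9
:D	2.3
;)	0.9
<3	2.4
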