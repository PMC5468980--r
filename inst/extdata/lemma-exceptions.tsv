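form	lemma
fell	fall
fallen	fall
falls	fall
given	give
gave	give
taken	take
took	take
went	go
gone	go
found	find
left	leave
fed	feed
bled	bleed
led	lead
lay	lie
lain	lie
lying	lie
dying	die
died	die
saw	see
seen	see
made	make
said	say
told	tell
got	get
gotten	get
came	come
became	become
began	begin
begun	begin
broke	break
broken	break
brought	bring
bought	buy
caught	catch
chose	choose
chosen	choose
did	do
done	do
drew	draw
drawn	draw
drank	drink
drunk	drink
ate	eat
eaten	eat
felt	feel
fought	fight
forgot	forget
forgotten	forget
froze	freeze
frozen	freeze
grew	grow
grown	grow
heard	hear
held	hold
hurt	hurt
kept	keep
knew	know
known	know
lost	lose
meant	mean
met	meet
paid	pay
put	put
ran	run
rang	ring
rung	ring
rose	rise
risen	rise
sent	send
set	set
shook	shake
shaken	shake
slept	sleep
spoke	speak
spoken	speak
stood	stand
struck	strike
swore	swear
sworn	swear
threw	throw
thrown	throw
understood	understand
woke	wake
woken	wake
wore	wear
worn	wear
wrote	write
written	write
men	man
women	woman
feet	foot
teeth	tooth
children	child
nurses	nurse
doses	dose
worse	bad
worst	bad
better	good
best	good
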