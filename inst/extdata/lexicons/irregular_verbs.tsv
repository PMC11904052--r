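form	lemma	tense	aux
am	be	present	auto
is	be	present	auto
are	be	present	auto
was	be	past	auto
were	be	past	auto
been	be	participle	aux
being	be	gerund	auto
be	be	base	auto
'm	be	present	auto
're	be	present	auto
's	be	present	auto
ai	be	present	auto
have	have	present	auto
has	have	present	auto
had	have	past	auto
having	have	gerund	auto
've	have	present	aux
do	do	present	aux
does	do	present	aux
did	do	past	aux
done	do	participle	aux
doing	do	gerund	aux
felt	feel	past	main
saw	see	past	main
seen	see	participle	main
wrote	write	past	main
written	write	participle	main
went	go	past	main
gone	go	participle	main
came	come	past	main
took	take	past	main
taken	take	participle	main
made	make	past	main
got	get	past	main
gotten	get	participle	main
thought	think	past	main
knew	know	past	main
known	know	participle	main
said	say	past	main
told	tell	past	main
ran	run	past	main
ate	eat	past	main
eaten	eat	participle	main
drank	drink	past	main
drunk	drink	participle	main
sat	sit	past	main
stood	stand	past	main
fell	fall	past	main
fallen	fall	participle	main
held	hold	past	main
caught	catch	past	main
drove	drive	past	main
driven	drive	participle	main
threw	throw	past	main
thrown	throw	participle	main
forgot	forget	past	main
forgotten	forget	participle	main
understood	understand	past	main
meant	mean	past	main
kept	keep	past	main
left	leave	past	main
lost	lose	past	main
found	find	past	main
gave	give	past	main
given	give	participle	main
sang	sing	past	main
sung	sing	participle	main
swam	swim	past	main
swum	swim	participle	main
fought	fight	past	main
spoke	speak	past	main
spoken	speak	participle	main
broke	break	past	main
broken	break	participle	main
wore	wear	past	main
worn	wear	participle	main
grew	grow	past	main
grown	grow	participle	main
flew	fly	past	main
flown	fly	participle	main
heard	hear	past	main
met	meet	past	main
paid	pay	past	main
rode	ride	past	main
rose	rise	past	main
sent	send	past	main
shook	shake	past	main
shaken	shake	participle	main
shot	shoot	past	main
won	win	past	main
tore	tear	past	main
bit	bite	past	main
bitten	bite	participle	main
hid	hide	past	main
hidden	hide	participle	main
drew	draw	past	main
drawn	draw	participle	main
built	build	past	main
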