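proprietary	generic
Seroxat	paroxetine
Paxil	paroxetine
Prozac	fluoxetine
Oxactin	fluoxetine
Efexor	venlafaxine
Effexor	venlafaxine
Cipramil	citalopram
Celexa	citalopram
Cipralex	escitalopram
Lustral	sertraline
Zoloft	sertraline
Tryptizol	amitriptyline
Elavil	amitriptyline
Anafranil	clomipramine
Sinequan	doxepin
Tofranil	imipramine
Surmontil	trimipramine
Allegron	nortriptyline
Prothiaden	dosulepin
Gamanil	lofepramine
Cymbalta	duloxetine
Zispin	mirtazapine
Faverin	fluvoxamine
Zyprexa	olanzapine
Clozaril	clozapine
Risperdal	risperidone
Abilify	aripiprazole
Haldol	haloperidol
Serenace	haloperidol
Modecate	fluphenazine
Fentazin	perphenazine
Orap	pimozide
Clopixol	zuclopenthixol
Melleril	thioridazine
Stemetil	prochlorperazine
Losec	omeprazole
Prilosec	omeprazole
Nexium	esomeprazole
Zoton	lansoprazole
Zantac	ranitidine
Diflucan	fluconazole
Zyban	bupropion
Lamisil	terbinafine
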