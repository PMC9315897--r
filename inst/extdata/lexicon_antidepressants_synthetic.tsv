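surface	language	category	concept_id	canonical
# Synthetic stand-in antidepressant dictionary: 35 active substances with
# ATC-style concept ids and 82 Spain-style brand names (real and invented
# names mixed). Replace via load_lexicon() for real analyses.
citalopram	both	drug_substance	N06AB04	citalopram
escitalopram	both	drug_substance	N06AB10	escitalopram
fluoxetina	both	drug_substance	N06AB03	fluoxetina
paroxetina	both	drug_substance	N06AB05	paroxetina
sertralina	both	drug_substance	N06AB06	sertralina
fluvoxamina	both	drug_substance	N06AB08	fluvoxamina
venlafaxina	both	drug_substance	N06AX16	venlafaxina
desvenlafaxina	both	drug_substance	N06AX23	desvenlafaxina
duloxetina	both	drug_substance	N06AX21	duloxetina
mirtazapina	both	drug_substance	N06AX11	mirtazapina
bupropion	both	drug_substance	N06AX12	bupropion
trazodona	both	drug_substance	N06AX05	trazodona
amitriptilina	both	drug_substance	N06AA09	amitriptilina
nortriptilina	both	drug_substance	N06AA10	nortriptilina
imipramina	both	drug_substance	N06AA02	imipramina
clomipramina	both	drug_substance	N06AA04	clomipramina
doxepina	both	drug_substance	N06AA12	doxepina
trimipramina	both	drug_substance	N06AA06	trimipramina
maprotilina	both	drug_substance	N06AA21	maprotilina
mianserina	both	drug_substance	N06AX03	mianserina
moclobemida	both	drug_substance	N06AG02	moclobemida
tranilcipromina	both	drug_substance	N06AF04	tranilcipromina
agomelatina	both	drug_substance	N06AX22	agomelatina
vortioxetina	both	drug_substance	N06AX26	vortioxetina
reboxetina	both	drug_substance	N06AX18	reboxetina
tianeptina	both	drug_substance	N06AX14	tianeptina
vilazodona	both	drug_substance	N06AX24	vilazodona
levomilnacipran	both	drug_substance	N06AX28	levomilnacipran
milnacipran	both	drug_substance	N06AX17	milnacipran
nefazodona	both	drug_substance	N06AX06	nefazodona
amoxapina	both	drug_substance	N06AA17	amoxapina
protriptilina	both	drug_substance	N06AA11	protriptilina
lofepramina	both	drug_substance	N06AA07	lofepramina
butriptilina	both	drug_substance	N06AA15	butriptilina
oxitriptan	both	drug_substance	N06AX01	oxitriptan
Seropram	both	drug_brand	N06AB04	citalopram
Prisdal	both	drug_brand	N06AB04	citalopram
Citalvir	both	drug_brand	N06AB04	citalopram
Cipralex	both	drug_brand	N06AB10	escitalopram
Esertia	both	drug_brand	N06AB10	escitalopram
Heipram	both	drug_brand	N06AB10	escitalopram
Prozac	both	drug_brand	N06AB03	fluoxetina
Adofen	both	drug_brand	N06AB03	fluoxetina
Reneuron	both	drug_brand	N06AB03	fluoxetina
Seroxat	both	drug_brand	N06AB05	paroxetina
Motivan	both	drug_brand	N06AB05	paroxetina
Frosinor	both	drug_brand	N06AB05	paroxetina
Besitran	both	drug_brand	N06AB06	sertralina
Aremis	both	drug_brand	N06AB06	sertralina
Sertrapin	both	drug_brand	N06AB06	sertralina
Dumirox	both	drug_brand	N06AB08	fluvoxamina
Luvoxam	both	drug_brand	N06AB08	fluvoxamina
Vandral	both	drug_brand	N06AX16	venlafaxina
Dobupal	both	drug_brand	N06AX16	venlafaxina
Venlabrain	both	drug_brand	N06AX16	venlafaxina
Pristiq	both	drug_brand	N06AX23	desvenlafaxina
Desvenix	both	drug_brand	N06AX23	desvenlafaxina
Cymbalta	both	drug_brand	N06AX21	duloxetina
Xeristar	both	drug_brand	N06AX21	duloxetina
Duloxor	both	drug_brand	N06AX21	duloxetina
Rexer	both	drug_brand	N06AX11	mirtazapina
Vastat	both	drug_brand	N06AX11	mirtazapina
Mirtaben	both	drug_brand	N06AX11	mirtazapina
Elontril	both	drug_brand	N06AX12	bupropion
Zyntabac	both	drug_brand	N06AX12	bupropion
Quomem	both	drug_brand	N06AX12	bupropion
Deprax	both	drug_brand	N06AX05	trazodona
Trazodil	both	drug_brand	N06AX05	trazodona
Tryptizol	both	drug_brand	N06AA09	amitriptilina
Elavil	both	drug_brand	N06AA09	amitriptilina
Amitril	both	drug_brand	N06AA09	amitriptilina
Paxtibi	both	drug_brand	N06AA10	nortriptilina
Norfenazin	both	drug_brand	N06AA10	nortriptilina
Tofranil	both	drug_brand	N06AA02	imipramina
Imidol	both	drug_brand	N06AA02	imipramina
Anafranil	both	drug_brand	N06AA04	clomipramina
Clomival	both	drug_brand	N06AA04	clomipramina
Sinequan	both	drug_brand	N06AA12	doxepina
Doxepar	both	drug_brand	N06AA12	doxepina
Surmontil	both	drug_brand	N06AA06	trimipramina
Trimidol	both	drug_brand	N06AA06	trimipramina
Ludiomil	both	drug_brand	N06AA21	maprotilina
Maprotol	both	drug_brand	N06AA21	maprotilina
Lantanon	both	drug_brand	N06AX03	mianserina
Miansec	both	drug_brand	N06AX03	mianserina
Manerix	both	drug_brand	N06AG02	moclobemida
Moclamur	both	drug_brand	N06AG02	moclobemida
Parnate	both	drug_brand	N06AF04	tranilcipromina
Tranilex	both	drug_brand	N06AF04	tranilcipromina
Valdoxan	both	drug_brand	N06AX22	agomelatina
Thymanax	both	drug_brand	N06AX22	agomelatina
Agomel	both	drug_brand	N06AX22	agomelatina
Brintellix	both	drug_brand	N06AX26	vortioxetina
Vortidix	both	drug_brand	N06AX26	vortioxetina
Irenor	both	drug_brand	N06AX18	reboxetina
Norebox	both	drug_brand	N06AX18	reboxetina
Zinosal	both	drug_brand	N06AX14	tianeptina
Tianepax	both	drug_brand	N06AX14	tianeptina
Viibryd	both	drug_brand	N06AX24	vilazodona
Vilazor	both	drug_brand	N06AX24	vilazodona
Fetzima	both	drug_brand	N06AX28	levomilnacipran
Levomil	both	drug_brand	N06AX28	levomilnacipran
Ixel	both	drug_brand	N06AX17	milnacipran
Savella	both	drug_brand	N06AX17	milnacipran
Dutonin	both	drug_brand	N06AX06	nefazodona
Rulivan	both	drug_brand	N06AX06	nefazodona
Demolox	both	drug_brand	N06AA17	amoxapina
Amoxan	both	drug_brand	N06AA17	amoxapina
Vivactil	both	drug_brand	N06AA11	protriptilina
Protival	both	drug_brand	N06AA11	protriptilina
Gamanil	both	drug_brand	N06AA07	lofepramina
Lofemin	both	drug_brand	N06AA07	lofepramina
Evadyne	both	drug_brand	N06AA15	butriptilina
Butripel	both	drug_brand	N06AA15	butriptilina
Cincofarm	both	drug_brand	N06AX01	oxitriptan
Telesol	both	drug_brand	N06AX01	oxitriptan
Triptanol	both	drug_brand	N06AX01	oxitriptan
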