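drug	class
citalopram	SSRI
escitalopram	SSRI
fluoxetine	SSRI
fluvoxamine	SSRI
paroxetine	SSRI
sertraline	SSRI
venlafaxine	SNRI
duloxetine	SNRI
mirtazapine	other_antidepressant
amitriptyline	TCA
clomipramine	TCA
doxepin	TCA
imipramine	TCA
trimipramine	TCA
nortriptyline	TCA
dosulepin	TCA
lofepramine	TCA
aripiprazole	antipsychotic
clozapine	antipsychotic
fluphenazine	antipsychotic
haloperidol	antipsychotic
olanzapine	antipsychotic
perphenazine	antipsychotic
pimozide	antipsychotic
risperidone	antipsychotic
zuclopenthixol	antipsychotic
thioridazine	antipsychotic
prochlorperazine	antipsychotic
omeprazole	other
esomeprazole	other
lansoprazole	other
ranitidine	other
fluconazole	other
bupropion	other
terbinafine	other
quinidine	other
cinacalcet	other
ticlopidine	other
moclobemide	other_antidepressant
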