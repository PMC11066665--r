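drug	cpz100_equiv_mg
chlorpromazine	100
quetiapine	75
olanzapine	5
aripiprazole	7.5
clozapine	50
risperidone	2
haloperidol	2
amisulpride	100
sertindole	4
flupentixol	3
perphenazine	8
ziprasidone	60
levomepromazine	70
zuclopenthixol	25
chlorprothixene	100
sulpiride	200
cariprazine	2.5
melperone	100
fluphenazine	2
paliperidone	3
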