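molecule,pap_count,long_acting_count
tiapride,1213,0
haloperidol,1036,339
sulpiride,829,0
amisulpride,649,0
loxapine,362,0
pipamperone,170,0
zuclopenthixol,156,0
chlorpromazine,111,0
periciazine,103,0
fluphenazine,88,0
flupentixol,56,0
pipotiazine,54,0
pimozide,51,0
carpipramine,41,0
penfluridol,6,0
perphenazine,3,0
chlorproethazine,0,0
droperidol,0,0
thioridazine,0,0
trifluoperazine,0,0
risperidone,2661,308
olanzapine,1636,0
aripiprazole,896,48
quetiapine,518,0
clozapine,179,0
paliperidone,52,52
cyamemazine,2581,0
levomepromazine,348,0
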