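molecule,generation,long_acting_available,long_acting_only
tiapride,FGAP,FALSE,FALSE
haloperidol,FGAP,TRUE,FALSE
sulpiride,FGAP,FALSE,FALSE
amisulpride,FGAP,FALSE,FALSE
loxapine,FGAP,FALSE,FALSE
pipamperone,FGAP,FALSE,FALSE
zuclopenthixol,FGAP,FALSE,FALSE
chlorpromazine,FGAP,FALSE,FALSE
periciazine,FGAP,FALSE,FALSE
fluphenazine,FGAP,FALSE,FALSE
flupentixol,FGAP,FALSE,FALSE
pipotiazine,FGAP,FALSE,FALSE
pimozide,FGAP,FALSE,FALSE
carpipramine,FGAP,FALSE,FALSE
penfluridol,FGAP,FALSE,FALSE
perphenazine,FGAP,FALSE,FALSE
chlorproethazine,FGAP,FALSE,FALSE
droperidol,FGAP,FALSE,FALSE
thioridazine,FGAP,FALSE,FALSE
trifluoperazine,FGAP,FALSE,FALSE
risperidone,SGAP,TRUE,FALSE
olanzapine,SGAP,FALSE,FALSE
aripiprazole,SGAP,TRUE,FALSE
quetiapine,SGAP,FALSE,FALSE
clozapine,SGAP,FALSE,FALSE
paliperidone,SGAP,TRUE,TRUE
cyamemazine,OTHER,FALSE,FALSE
levomepromazine,OTHER,FALSE,FALSE
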