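classifier,CBSO,NDBM,CBM,DBM,MSMOTE,ProWSyn,Random_SMOTE,SMOTE_TomekLinks,SMOTE
KNN,1,7,9,4,5,8,2,6,3
LR,1,8,3,9,2,5,6,7,4
MLP,3,8,9,7,1,5,2,4,6
RF,1,6,9,4,7,8,3,5,2
SVM,1,8,7,9,2,3,6,4,5
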