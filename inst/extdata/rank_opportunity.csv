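classifier,CBSO,NDBM,CBM,DBM,MSMOTE,ProWSyn,Random_SMOTE,SMOTE_TomekLinks,SMOTE
KNN,5,6,9,7,1,4,8,3,2
LR,5,9,7,8,1,2,6,4,3
MLP,5,7,9,8,1,3,2,4,6
RF,4,5,8,3,1,9,7,6,2
SVM,2,7,8,9,1,4,3,5,6
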