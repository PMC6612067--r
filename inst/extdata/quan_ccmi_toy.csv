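code,category,weight
I21*,Myocardial infarction,1
I22*,Myocardial infarction,1
I252,Myocardial infarction,1
I50*,Congestive heart failure,1
I110,Congestive heart failure,1
I70*,Peripheral vascular disease,1
I71*,Peripheral vascular disease,1
G45*,Cerebrovascular disease,1
I60*,Cerebrovascular disease,1
I61*,Cerebrovascular disease,1
I62*,Cerebrovascular disease,1
I63*,Cerebrovascular disease,1
I64*,Cerebrovascular disease,1
I65*,Cerebrovascular disease,1
I66*,Cerebrovascular disease,1
I67*,Cerebrovascular disease,1
I69*,Cerebrovascular disease,1
F00*,Dementia,1
F01*,Dementia,1
F02*,Dementia,1
F03*,Dementia,1
G30*,Dementia,1
J40*,Chronic pulmonary disease,1
J41*,Chronic pulmonary disease,1
J42*,Chronic pulmonary disease,1
J43*,Chronic pulmonary disease,1
J44*,Chronic pulmonary disease,1
J45*,Chronic pulmonary disease,1
J47*,Chronic pulmonary disease,1
M05*,Rheumatic disease,1
M06*,Rheumatic disease,1
M32*,Rheumatic disease,1
M33*,Rheumatic disease,1
K25*,Peptic ulcer disease,1
K26*,Peptic ulcer disease,1
K27*,Peptic ulcer disease,1
K28*,Peptic ulcer disease,1
B18*,Mild liver disease,1
K73*,Mild liver disease,1
K74*,Mild liver disease,1
E10*,Diabetes without chronic complication,1
E11*,Diabetes without chronic complication,1
E102,Diabetes with chronic complication,2
E112,Diabetes with chronic complication,2
E113,Diabetes with chronic complication,2
E114,Diabetes with chronic complication,2
G81*,Hemiplegia or paraplegia,2
G82*,Hemiplegia or paraplegia,2
N18*,Renal disease,2
N19*,Renal disease,2
C18*,Any malignancy,2
C34*,Any malignancy,2
C50*,Any malignancy,2
C81*,Any malignancy,2
C91*,Any malignancy,2
K704,Moderate or severe liver disease,3
K72*,Moderate or severe liver disease,3
I85*,Moderate or severe liver disease,3
C77*,Metastatic solid tumour,6
C78*,Metastatic solid tumour,6
C79*,Metastatic solid tumour,6
C80*,Metastatic solid tumour,6
B20*,AIDS/HIV,6
B24,AIDS/HIV,6
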