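code,category
S00*,Superficial injury; contusion
S30*,Superficial injury; contusion
J06*,Other upper respiratory infections
S93*,Sprains and strains
K52*,Non-infectious gastroenteritis
S61*,Open wounds of extremities
S81*,Open wounds of extremities
K29*,Gastritis and duodenitis
S52*,Fracture of upper limb
S62*,Fracture of upper limb
S72*,Fracture of lower limb
S82*,Fracture of lower limb
I10*,Essential hypertension
I25*,Coronary atherosclerosis and other heart disease
I21*,Acute myocardial infarction
I22*,Acute myocardial infarction
I6*,Acute cerebrovascular disease
J12*,Pneumonia
J18*,Pneumonia
N39*,Urinary tract infections
A40*,Septicemia (except in labour)
A41*,Septicemia (except in labour)
F31*,Mood disorders
F32*,Mood disorders
F33*,Mood disorders
F2*,Schizophrenia and other psychotic disorders
O80*,Normal pregnancy and delivery
Z37*,Normal pregnancy and delivery
H25*,Cataract
H26*,Cataract
O70*,Other complications of birth
O72*,Other complications of birth
C50*,Cancer of breast
N97*,Female infertility
H57*,Other eye disorders
T30*,Burns
T31*,Burns
S06*,Intracranial injury
N17*,Acute and unspecified renal failure
N18*,Chronic kidney disease
C91*,Leukemias
C82*,Non-Hodgkin lymphoma
C18*,Cancer of colon
I50*,Congestive heart failure; nonhypertensive
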