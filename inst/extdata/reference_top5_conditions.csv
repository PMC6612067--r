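group,rank,condition,patients_ever
Non-HU,1,Superficial injury; contusion,27049
Non-HU,2,Other upper respiratory infections,14778
Non-HU,3,Sprains and strains,14546
Non-HU,4,Non-infectious gastroenteritis,12371
Non-HU,5,Open wounds of extremities,11447
Cost,1,Coronary atherosclerosis and other heart disease,2946
Cost,2,Acute myocardial infarction,2877
Cost,3,Acute cerebrovascular disease,879
Cost,4,Essential hypertension,781
Cost,5,Fracture of lower limb,604
LOS,1,Mood disorders,52
LOS,2,Schizophrenia and other psychotic disorders,36
LOS,3,Residual codes; unclassified,17
LOS,4,Pneumonia,13
LOS,5,Intracranial injury,12
SOC,1,Normal pregnancy and delivery,3490
SOC,2,Cataract,1379
SOC,3,Other complications of birth,1151
SOC,4,Fracture of upper limb,1055
SOC,5,Gastritis and duodenitis,743
LOS-SOC,1,Mood disorders,23
LOS-SOC,2,Schizophrenia and other psychotic disorders,14
LOS-SOC,3,Other eye disorders,5
LOS-SOC,4,Superficial injury; contusion,5
LOS-SOC,5,Burns,4
Cost-LOS,1,Acute cerebrovascular disease,1049
Cost-LOS,2,Pneumonia,838
Cost-LOS,3,Urinary tract infections,546
Cost-LOS,4,Coronary atherosclerosis and other heart disease,493
Cost-LOS,5,Acute myocardial infarction,417
Cost-SOC,1,Cancer of breast,955
Cost-SOC,2,Coronary atherosclerosis and other heart disease,925
Cost-SOC,3,Female infertility,650
Cost-SOC,4,Fracture of upper limb,619
Cost-SOC,5,Essential hypertension,581
Cost-LOS-SOC,1,Coronary atherosclerosis and other heart disease,572
Cost-LOS-SOC,2,Acute cerebrovascular disease,440
Cost-LOS-SOC,3,Pneumonia,414
Cost-LOS-SOC,4,Essential hypertension,398
Cost-LOS-SOC,5,Septicemia (except in labour),363
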