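group,n,persistence_n,death_n
Non-HU,322905,7108,4625
Cost,14647,774,1460
LOS,217,19,20
SOC,26179,3819,90
LOS-SOC,44,11,0
Cost-LOS,6008,651,1626
Cost-SOC,12892,3244,247
Cost-LOS-SOC,5270,1863,654
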