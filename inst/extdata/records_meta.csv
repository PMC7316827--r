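record,dataset,duration_min,physionet_shared
B1_Pregnancy_01,B1,20,0
B1_Pregnancy_02,B1,20,0
B1_Pregnancy_03,B1,20,0
B1_Pregnancy_04,B1,20,0
B1_Pregnancy_05,B1,20,0
B1_Pregnancy_06,B1,20,0
B1_Pregnancy_07,B1,20,0
B1_Pregnancy_08,B1,20,0
B1_Pregnancy_09,B1,20,0
B1_Pregnancy_10,B1,20,0
B2_Labour_01,B2,5,1
B2_Labour_02,B2,5,0
B2_Labour_03,B2,5,0
B2_Labour_04,B2,5,1
B2_Labour_05,B2,5,0
B2_Labour_06,B2,5,0
B2_Labour_07,B2,5,1
B2_Labour_08,B2,5,1
B2_Labour_09,B2,5,0
B2_Labour_10,B2,5,1
B2_Labour_11,B2,5,0
B2_Labour_12,B2,5,0
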