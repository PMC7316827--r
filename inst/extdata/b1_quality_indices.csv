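record,WM,WF,WEM,WEF
B1_Pregnancy_01,16.5,5.3,0.05,0.45
B1_Pregnancy_02,14.1,4.1,0.08,0.48
B1_Pregnancy_03,15.0,5.0,0.09,0.40
B1_Pregnancy_04,12.5,4.0,0.14,0.51
B1_Pregnancy_05,17.5,8.1,0.06,0.18
B1_Pregnancy_06,12.9,4.4,0.11,0.31
B1_Pregnancy_07,11.6,0.8,0.11,1.06
B1_Pregnancy_08,10.9,-1.6,0.10,0.41
B1_Pregnancy_09,16.9,-0.7,0.05,0.79
B1_Pregnancy_10,14.9,5.1,0.07,0.59
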