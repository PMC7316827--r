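record,WM,WF,WEM,WEF
B2_Labour_01,10.6,6.7,0.20,0.20
B2_Labour_02,12.6,5.0,0.10,0.25
B2_Labour_03,7.8,-2.7,0.30,0.54
B2_Labour_04,11.7,2.3,0.13,0.31
B2_Labour_05,9.7,5.9,0.28,0.20
B2_Labour_06,12.8,3.7,0.10,0.19
B2_Labour_07,11.4,0.5,0.27,0.67
B2_Labour_08,10.6,7.0,0.18,0.18
B2_Labour_09,11.4,3.9,0.15,0.44
B2_Labour_10,11.6,0.7,0.11,0.48
B2_Labour_11,8.4,6.6,0.21,0.16
B2_Labour_12,6.5,3.8,0.36,0.28
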