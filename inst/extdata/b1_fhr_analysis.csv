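record,loss_pct,basal,fluctuation,acc_count,dec_count,oscillation,ltv_dawes,stv_dawes,lti,sti,ii,di
B1_Pregnancy_01,0.2,156.3,14.1,10,0,17.5,43.3,5.2,25.1,0.0113,0.0076,8.8
B1_Pregnancy_02,0.6,140.3,11.2,0,1,17.9,58.6,8.9,28.6,0.0128,0.0087,15.3
B1_Pregnancy_03,0.6,128.3,7.2,5,0,10.3,38.8,10.1,31.0,0.0201,0.0050,13.6
B1_Pregnancy_04,0.0,139.0,11.7,3,0,10.5,32.1,4.0,17.6,0.0080,0.0053,5.8
B1_Pregnancy_05,0.2,138.8,10.5,4,0,10.5,25.3,2.9,11.4,0.0054,0.0037,4.4
B1_Pregnancy_06,0.2,144.7,11.3,2,0,9.0,25.8,3.7,12.9,0.0070,0.0042,5.9
B1_Pregnancy_07,1.0,155.9,15.4,2,0,13.6,34.2,6.6,14.6,0.0112,0.0057,12.2
B1_Pregnancy_08,0.6,145.8,12.5,5,0,14.3,39.8,5.5,21.7,0.0091,0.0065,9.4
B1_Pregnancy_09,2.5,143.5,11.6,3,0,10.2,30.0,4.2,17.1,0.0080,0.0049,6.6
B1_Pregnancy_10,11.2,132.3,10.0,6,2,15.7,54.1,12.6,45.8,0.0226,0.0075,18.1
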