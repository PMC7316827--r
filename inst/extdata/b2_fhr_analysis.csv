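record,loss_pct,basal,fluctuation,acc_count,dec_count,oscillation,ltv_dawes,stv_dawes,lti,sti,ii,di
B2_Labour_01,1.7,128.7,7.2,2,0,12.9,44.9,6.1,20.1,0.0081,0.0065,10.3
B2_Labour_02,5.8,131.9,7.6,1,0,19.9,66.8,9.5,46.9,0.0163,0.0108,13.9
B2_Labour_03,27.5,152.4,14.7,0,0,20.9,52.7,6.8,21.0,0.0101,0.0077,12.9
B2_Labour_04,2.5,137.5,9.2,2,0,14.8,46.7,9.3,28.8,0.0182,0.0071,13.3
B2_Labour_05,1.7,132.0,6.9,3,0,18.6,66.1,10.5,35.7,0.0122,0.0081,16.9
B2_Labour_06,0.0,136.7,9.5,1,0,10.4,33.4,3.1,19.7,0.0046,0.0057,5.0
B2_Labour_07,0.0,126.2,6.4,2,1,14.3,51.9,10.0,57.1,0.0169,0.0080,13.7
B2_Labour_08,0.0,128.9,7.2,0,0,10.4,36.9,6.1,12.9,0.0092,0.0048,9.0
B2_Labour_09,0.8,134.7,9.0,0,0,10.7,36.3,4.0,19.5,0.0070,0.0054,5.8
B2_Labour_10,0.0,125.4,6.7,0,0,8.4,33.1,4.6,10.6,0.0075,0.0043,6.3
B2_Labour_11,3.3,130.3,7.1,2,0,16.8,56.9,9.5,35.6,0.0141,0.0086,14.9
B2_Labour_12,0.0,131.3,8.1,0,0,8.0,28.0,4.3,18.3,0.0076,0.0044,6.1
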