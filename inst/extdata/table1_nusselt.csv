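N_T,N_B,M,beta_e,beta_i,beta_F,Nu,ANN,Error
1.5,0.5,1,0.1,0.1,1,0.315924,0.315589,0.000335
2,0.5,1,0.1,0.1,1,0.235448,0.235875,-0.00043
2.5,0.5,1,0.1,0.1,1,0.138782,0.171534,-0.03275
1,1,1,0.1,0.1,1,0.353109,0.360916,-0.00781
1,1.5,1,0.1,0.1,1,0.317912,0.31871,-0.0008
1,2,1,0.1,0.1,1,0.274622,0.272281,0.00234
1,0.5,1.5,0.1,0.1,1,0.375097,0.375265,-0.00017
1,1,2,0.1,0.1,1,0.35933,0.360059,-0.00073
1,0.5,2.5,0.1,0.1,1,0.324302,0.324551,-0.00025
1,0.5,1,1,0.1,1,0.38038,0.376992,0.003387
1,0.5,1,2,0.1,1,0.3805,0.380314,0.000187
1,0.5,1,3,0.1,1,0.380577,0.338641,0.041936
1,0.5,1,0.1,1,1,0.380799,0.381286,-0.00049
1,0.5,1,0.1,2,1,0.380775,0.383018,-0.00224
1,0.5,1,0.1,3,1,0.38071,0.380908,-0.0002
1,0.5,1,0.1,0.1,0,0.370398,0.370201,0.000196
1,0.5,1,0.1,0.1,2,0.390023,0.389251,0.000772
1,0.5,1,0.1,0.1,3,0.399835,0.399723,0.000112
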