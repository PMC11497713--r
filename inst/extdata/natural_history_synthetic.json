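{"time_years":[0,0.25,0.5,0.75,1,1.25,1.5,1.75,2,2.25,2.5,2.75,3,3.25,3.5,3.75,4,4.25,4.5,4.75,5,5.25,5.5,5.75,6,6.25,6.5,6.75,7,7.25,7.5,7.75,8,8.25,8.5,8.75,9,9.25,9.5,9.75,10,10.25,10.5,10.7,10.75,11,11.1,11.25,11.5,11.75,12,12.25,12.5,12.75,13,13.25,13.5,13.75,14,14.25,14.5,14.75,15,15.25,15.5,15.75,16,16.25,16.5,16.75,17,17.25,17.5,17.7,17.75,18,18.25,18.5,18.75,19,19.25,19.5,19.75,20,20.25,20.5,20.75,21],"cdr_sb":[0,0.0598312165178571,0.115072946428571,0.166097310267857,0.213276428571429,0.256982421875,0.297587410714286,0.335463515625,0.370982857142857,0.404517555803571,0.436439732142857,0.467121506696428,0.496935,0.526252332589286,0.555445624999999,0.584886997767857,0.614948571428571,0.646002466517857,0.678420803571428,0.712575703124999,0.748839285714285,0.787583671875,0.829180982142857,0.87400333705357,0.922422857142857,0.974811662946428,1.031541875,1.09298561383929,1.159515,1.23150215401786,1.30931919642857,1.39333824776786,1.48393142857143,1.581470859375,1.68632866071429,1.798876953125,1.91948785714286,2.04853349330357,2.18638598214286,2.33341744419643,2.49,2.70663019314869,2.98976093294461,3.22,3.27348958333333,3.54383928571429,3.68,3.91076534325695,4.31453460222055,4.74041025570791,5.18626455672427,5.6499697582749,6.12939811336506,6.622421875,7.12691329618499,7.64074462992529,8.16178812922615,8.68791604709283,9.2170006365306,9.74691415054471,10.2755288421404,10.800716964323,11.3203507700977,11.8323025124697,12.3344444444444,12.824648819027,13.3007878892228,13.760733908037,14.2023591284748,14.6235358035416,15.0221361862426,15.396032529583,15.7430970865682,16,16.0608704121101,16.3380916604057,16.5740740740741,16.7742438155661,16.9440270473328,17.0888499318251,17.214138631494,17.3253193087904,17.4278181261652,17.5270612460695,17.6284748309542,17.7374850432702,17.8595180454685,18],"positivity_threshold_centiloids":24.1}
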