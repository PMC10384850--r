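-0.0137140780318,0.221011955119
0.181677402624,-0.00837213231336
-0.136744635782,0.0603474140262
0.296516456873,0.115706265553
0.206130938389,-0.197030548747
-0.148462889236,-0.0882430154374
0.271323991839,0.108996508953
-0.114117971992,-0.0421403857589
-0.249467672096,-0.202946840096
0.209048549887,0.185517115584
0.0473071994024,0.155492230169
0.00701950017191,-0.127465272136
-0.341372571626,0.192255883347
-0.316984252612,-0.0382391055491
-0.135580444734,-0.345237560278
-0.141286151429,0.113904593937
0.026459906853,-0.244444013562
0.0707048091091,0.197375161423
0.0109775333244,0.00752468919254
-0.118786770789,0.215066997485
0.0259890271706,-0.147104518429
-0.0678671723568,-0.133308355826
-0.0715833159637,0.0281244475799
0.0193078135555,0.0680421799747
0.285902868403,0.132992224116
-0.177067759192,0.125238931035
-0.103680010187,-0.140523459001
0.296647759392,-0.173315811903
0.0149355762991,0.041988313506
0.0271753446657,0.155064428173
0.011171734752,-0.128826302009
-0.0639366575056,0.257008403241
0.0214036325264,-0.0365444668892
0.0330725664787,-0.132764466293
-0.0986526308248,-0.121919652704
-0.173154988145,0.104592503778
0.146195418285,-0.356835540238
0.174388525149,-0.0132742376288
0.0260325761977,0.0096960189297
0.0630708410939,0.182589419675
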