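-0.495038695239,0.161180198148,0.544825361916,0.0406698084714,-0.108229558054
-0.70405047517,0.242384845308,0.0572483986474,-0.00788127254027,-0.109112332298
0.610342784407,-0.274410347429,-0.0875088358045,-0.147796228253,-0.138624354731
-0.742258240042,-0.240679533158,-0.00206194560733,-0.0804199248655,0.180650326087
-0.478152512581,0.182209111064,-0.384513038003,0.0130707185669,-0.102830104554
0.633945117215,-0.126661089265,0.171342939158,0.351491532299,0.0975566100782
-0.743185802093,-0.138928063372,0.123183113523,0.0108464049718,0.187590802835
0.108394571726,0.408435508873,-0.0163875910394,-0.19189389883,-0.0493851508139
1.20141780404,0.26748556197,-0.266214145716,-0.142051266762,0.194799073547
-0.381756011844,-0.735006494282,-0.155020466068,0.0951530723627,-0.1077210143
-0.0802149611177,-0.439924400159,-0.104136027771,-0.152544016861,-0.00932150729605
0.219241206477,-0.0987181947705,-0.461970144396,0.0219405332177,0.0309009865433
0.557933712338,0.0826624407103,0.769624494097,0.0418033681674,0.0598891491596
0.923439374137,0.422965769877,0.260641472525,-0.0610680157714,-0.132083805481
0.365618244647,0.937016773614,-0.0166447401473,0.175751028429,-0.159791109599
0.185547203729,-0.0658853017544,0.296052858701,0.0565841809156,0.0363954360013
0.00173362997057,0.350619856971,-0.180772749324,0.144448477306,0.107716201928
-0.0562514105743,-0.755481669233,0.0404933465668,0.0441961838633,-0.0328871682787
-0.171921740579,0.144996893969,-0.073679578242,-0.130234796549,-0.0260882826505
0.452775300349,-0.650442099129,0.218029427845,-0.196439703101,0.10464708879
-0.131472409333,0.351067179127,-0.212460398011,-0.110317281613,0.0415188603393
0.586573703336,-0.182565399504,-0.330904713103,0.124686381537,-0.0101289207657
-0.148644373923,0.294015798382,0.22373048357,-0.0324955245583,0.0854873143195
0.0105695348364,-0.30883581934,-0.07241489691,0.0103343824654,0.0295495825817
-0.654957525228,-0.406653961754,-0.034241664212,0.0169232104246,0.140320755943
0.0493670493939,0.218113226991,0.353513272491,-0.0616190713072,0.0874102440612
0.0920579028236,0.582308361364,0.0165935580541,-0.100596419364,0.0428549167092
-0.626643711649,0.0217892100204,-0.423364996893,0.0612356023608,-0.151462303587
-0.157922193534,0.0487103706487,-0.104202850944,-0.154301889377,-0.0518596500617
-0.210533553391,-0.251129322656,0.258089126677,0.176408181168,-0.0728737317131
0.220753347708,-0.149441347528,-0.394059260846,0.0932426829578,0.076542678695
-0.0210416915537,-0.351329794466,0.317154309092,-0.0864232733676,-0.0982443545841
-0.191186855993,0.143013207637,0.121034982293,0.149014206011,0.0347920312844
-0.064120658149,0.240607874189,-0.334683635968,-0.129272171025,-0.015006138308
0.974140328561,-0.48969451419,-0.347661513801,0.0930797381532,-0.117366970155
0.495632123058,-0.223340065514,0.250876630762,0.00464692420908,-0.0313443623805
-0.376444800132,0.577539836227,-0.272126701567,0.115762800484,0.177808354888
-0.642547844604,0.189599841648,0.0962633204553,0.0816692322787,-0.0747831430702
-0.114775778907,-0.00717690299654,-0.0874083292039,-0.0289528442451,-0.0211003336162
-0.496361693122,0.0295824537623,0.243741127203,-0.108651052228,-0.0961861174939
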