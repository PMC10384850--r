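-0.222028036044,0.296577815654,0.0797242138446,0.349316219097,-0.293629736761
-0.471495672893,0.410626342479,-0.186829130768,-0.0673713267332,-0.369461470914
0.627537224872,-0.0867689569565,-0.156834282,-0.178967279206,-0.192104446802
-0.220249139835,0.734069410326,-0.2062244061,-0.0206741056744,0.228828395725
-0.487810695852,0.0365209468839,-0.153998380653,-0.347244046682,-0.172785334773
0.503110102133,-0.0640608538792,-0.292275916714,0.176776438975,-0.165814537116
-0.247663838334,0.723366185083,-0.210481190007,0.0166369657385,0.120628346344
-0.233337534013,-0.529170577447,-0.083104674451,0.140339829524,0.262502014459
0.335668604636,0.0279255484093,-0.52445291447,0.0154284041558,-0.0123916123333
0.129426272193,0.460480637636,0.205346044667,-0.1276968086,0.568321340791
0.308468876619,0.147565445612,0.528835409114,-0.255482628997,0.206450959606
0.335617639204,-0.256971342129,-0.043406707031,-0.473068175639,-0.0921045539787
0.216004112211,0.0423702942284,-0.217483125821,0.526814077039,0.0124318716676
0.276905548875,-0.0768776450905,-0.45530493903,0.407987348456,0.118051177154
-0.0827573071031,-0.227577452696,-0.381186825531,0.240590603985,0.465258587978
0.304095490962,-0.161797457424,0.224163601566,0.484229181916,-0.153430179604
-0.293275665709,-0.488650889644,-0.116236579484,-0.10250833096,0.167420221075
0.356404619206,0.304880674471,0.391132307072,-0.15481737907,0.406298119516
-0.403417243244,-0.368068966043,0.233901513036,-0.131615407275,-0.0786312198665
0.572361786902,0.0964110411879,0.107314697477,-0.0603740623976,-0.0307585330297
-0.455551694106,-0.478671984267,-0.0695807693236,-0.197458723991,0.142140060882
0.589337174387,-0.122274690889,-0.307594980403,-0.317106061546,-0.21742027252
-0.329418634722,-0.313178340022,0.162726957626,0.379479878821,-0.0885974332735
0.350381423411,-0.0139406901322,0.510328017671,-0.240521721877,0.0214867408616
-0.142543831522,0.707065762963,-0.113787515387,-0.0328486833419,0.379175790302
-0.0141707036069,-0.239317356418,0.115401985138,0.621168337405,-0.0549093607775
-0.278290760717,-0.502305365168,-0.200404901218,0.205385536372,0.370032654701
-0.378317713357,0.334714171551,-0.200373306115,-0.276251210064,-0.148375563694
-0.293692139648,-0.299757767939,0.32867312091,-0.188478973018,-0.0876122081975
0.0419383276581,0.275248207812,0.502933544752,0.207411237042,-0.0248314607444
0.399657469493,-0.222567057256,-0.0179588610791,-0.450323710427,-0.117944721425
0.280764343929,0.136755226716,0.52700839764,0.227231669349,0.00219525635832
-0.333305879845,-0.176401906182,0.275806774077,0.179228634245,-0.211798557706
-0.338009516039,-0.47749792533,-0.0272300902176,-0.312184940278,0.120943878441
0.475042456486,0.0622390523777,-0.408445837916,-0.217871431046,-0.173252605563
0.581204563556,-0.0980963884028,-0.0266175577632,0.235620551908,-0.184329350631
-0.395551254235,-0.131411183474,-0.274672190843,-0.179472581436,0.0686756041457
-0.498817511702,0.439584470823,-0.125484639908,-0.03755272896,-0.373586517833
-0.177790243821,-0.27009966293,0.407351921972,-0.17867509642,-0.109750285951
-0.386431020384,0.369063225508,0.199321215672,0.134920499612,-0.307321056511
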