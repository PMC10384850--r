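-1.07787114285,1.95510051054,-0.655496481259,0.586204846166
0.0875284572636,0.910894368621,-1.1919501991,-0.926047240826
-0.744918481588,-1.66003571312,0.373921613013,0.297393360123
1.16947044039,0.843625703678,-1.55853546795,0.701579171001
1.00009830544,-0.184467774724,-0.664628317252,-1.43650083051
1.38800923313,1.0497804984,1.97679820356,1.35426763535
1.20532540324,1.46182681413,-1.29447013412,0.787545725822
-1.55594981057,-0.584776942639,-0.0275551493439,-1.36659175235
0.254902521752,-0.976234061329,2.10110912039,-0.298550827118
0.795595299234,-0.982400172973,-1.36482276845,1.3838431346
-0.615390553847,-1.57167264653,-0.982254221018,0.452403764835
0.938375251855,-1.19744482727,0.4627551919,-0.341613169539
-1.43360627867,1.9095263407,1.45625532279,1.54023221263
-1.07472972394,0.457694798425,1.74562975476,0.0768336736649
0.311627249016,1.41401426946,1.81647330181,-1.28260421589
-0.780740921609,0.509934633294,0.46611535442,0.785449540085
0.989679404849,0.557131034342,0.798550722882,-0.870053926148
0.3236416008,-1.0048429983,-0.649263365353,1.63761927602
-0.857273194097,-0.599275368039,-0.61915564152,-0.995374534601
-1.04861625667,-1.48901556872,-0.0670243912999,1.30354655666
-0.32364665493,-0.447622330169,-0.181314381599,-1.61574737413
1.226196666,-0.827891157678,1.21972552596,0.370493238365
-0.992465216531,0.769926833397,-0.0223299631087,-0.453710973534
0.0887337057383,-0.782235518608,-0.249512252591,0.530900111733
1.33091069345,0.568311665824,-1.43037715787,1.09154388187
-1.58954142012,0.805888342109,0.24311543165,0.113162805345
-0.953038994123,0.197436589402,0.445357847877,-1.39847707106
1.69585110181,-0.0228191980363,-0.949646988195,-0.940489671021
-0.957099754363,-0.934669279984,-0.789862214455,-0.848919770943
0.10394179797,0.811890037452,-0.283134263262,1.23016825949
1.23156114489,-0.86533375777,0.628705833389,0.000708477296107
-1.47119488722,-0.337631696777,-0.658812877249,1.08029459112
0.305955972692,1.01395225613,0.1674504053,-0.00370004309892
-0.214708964545,-0.961000505209,-0.223827322324,-1.54760431764
1.47126505897,-1.52427014971,1.53962241926,0.924126551328
-0.705175570742,-0.243539742165,0.703772008715,0.929159672916
1.34105435837,0.907300466195,0.293743550059,-1.88320383494
0.473967686954,1.18391406764,-0.879217446039,-0.494750962927
-0.279120419162,-0.493229533209,-0.398806612347,-0.380418105623
-1.05860310825,0.362259713215,-1.29710399201,-0.0931178645337
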