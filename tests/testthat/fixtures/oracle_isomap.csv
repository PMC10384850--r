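-2.96724739604,-0.00675240092103,3.02137766796
-5.02706800703,0.596875951821,0.925409821184
3.964925224,-1.85850149688,-1.00248536354
-5.44080428865,-2.83193088126,0.310757705071
-3.06736426317,2.14936083111,-1.84607334389
4.21546335968,-1.06122110855,1.64923066175
-5.32416457738,-2.46471025671,0.582650318154
0.0690367701157,3.23492726811,0.584014487482
6.71683169462,0.644165138669,-0.491083755353
-1.49008146266,-5.03370325868,-1.14694604271
0.570691524377,-2.09596214637,-1.36305339744
2.11913899059,0.212910555944,-2.78501144731
2.87021900291,-0.107320217223,4.26507020863
3.80822845917,1.76156740675,2.93523918864
1.53767505013,5.52046936929,1.31389179329
1.47813306317,-1.04237121897,2.51712238379
0.0902738533516,2.67176377031,-1.17033452449
0.420206790271,-3.89450217432,-1.10912459221
-0.914904923485,1.31265844374,-0.751272668701
3.22693028302,-3.19432339139,-0.0666775501327
-0.611235314881,2.66535936762,-1.68159582523
3.75296425708,-0.790715278846,-1.99213165599
-0.448351726906,1.78887495536,1.78353023138
0.980049687555,-1.6146458495,-0.906071368759
-4.79691536161,-3.65101378746,0.239533960579
0.874547172785,1.45330367612,2.62014546254
0.0341913150584,3.84058038952,0.61548133663
-4.99138179315,1.50116690246,-1.79547871377
-0.655109093418,0.762832986555,-1.19988400604
-0.967521840056,-2.20489977646,0.99216154603
2.2523306644,-0.0828820618419,-2.45292765718
0.589666967699,-2.4430089426,0.900316138175
-1.06590122398,0.665152910644,1.13516838111
-0.134028078927,2.34034119071,-2.11802392842
5.60453755253,-1.09492284412,-2.47769341883
3.18640760288,-1.75504785525,1.97466571998
-2.57842760369,3.72782257913,-2.17936578554
-4.519848178,0.413202953243,1.07441054825
-0.284851700368,0.290338698352,-1.04253354809
-3.077242452,-0.325240398088,0.137591032982
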