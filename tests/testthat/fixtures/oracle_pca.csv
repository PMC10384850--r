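-2.54742003239,0.593428547694,-3.10469718791,0.0826337251225,-0.0140020299514
-3.99011712023,1.64763758475,-0.116615049751,-0.0992011980003,-0.0258549063798
3.03298980228,-1.45212171917,0.657561247521,-0.795347726771,0.00036613654367
-4.9161198055,-1.5675825203,-0.0754332202879,0.586421801256,0.00248213371345
-2.44463267228,1.61089891552,2.00472727936,0.0156455801382,0.0155314268634
3.12162752363,-0.765715228644,-0.681617449395,1.77215274611,-0.0144140741183
-4.90025820243,-1.08317816696,-0.683670614758,0.899860074763,-0.030199327132
1.02811635593,2.18604896852,-0.00466606900026,-1.20000374154,-0.0096303350537
5.54146960268,0.678171468253,1.19625160133,0.269696148445,0.0370796841081
-2.24421581205,-3.98050986746,0.839663316194,-0.0662582236022,0.00847228982782
-0.213844716714,-2.34943825094,0.674292766649,-1.01980627852,0.0133059353621
1.53416728314,-0.437442927665,2.1373449181,0.103963957553,0.0353732904705
2.90325844555,0.138182050436,-4.10011013532,0.589077822351,0.0407815807315
4.28021557004,1.41313704955,-1.53891955927,0.0892739239331,-0.046989385984
2.21205253315,4.089124169,-0.33219618603,0.889258552635,0.0167930010297
1.3228000353,-0.432258019208,-1.69067810532,0.0449980798789,0.0098975537695
0.404724629041,2.01682545495,0.87152077945,0.734342097874,-0.030186601545
-0.194294112647,-3.93005016119,0.236128787826,-0.0806268966731,0.00937902472148
-0.637976525973,1.07589623022,0.43985720841,-0.951301117323,-0.0223270783254
2.36503943573,-3.1082204893,-0.375814675954,-0.827935955623,-0.00568065200106
-0.307876892424,2.29498296333,1.14122764402,-0.630447653897,-0.00692483635306
2.97552021789,-1.00940477354,1.5664237363,0.684554077989,-0.0231805856731
-0.327538055612,1.6345989445,-1.32012086112,-0.300152547971,0.0146733728498
0.299553167552,-1.66112325665,0.486279781964,-0.202296363354,0.00185872950348
-4.32717948007,-2.41434869169,0.0735992326428,0.667815187765,0.0102385445176
0.806200256865,1.02573273052,-2.25941473016,-0.417312164619,0.0122875761026
0.975833553938,2.94796407459,-0.193108550822,-0.519003877447,0.0124857355157
-3.53137810565,0.592857330171,2.18814098971,0.422798808888,-0.00786740343093
-0.597190280595,0.503162006722,0.5786872016,-1.13527215187,-0.0031244369533
-1.10597247174,-1.53532230248,-1.4081430013,0.466728659126,-0.0245397883706
1.52395552636,-0.727843991065,1.87081785255,0.462099213406,-0.0158350066175
0.0730974590143,-1.98300843153,-1.64679437642,-0.823018936695,-0.000907883547696
-0.788137741699,0.832518631158,-0.669650371979,0.543258940119,-0.0254157708085
0.0460246883213,1.71340827266,1.67379656692,-0.754598688727,-0.0339228655962
4.41643622165,-2.39579904683,2.06674085078,0.736942539238,0.0233457219406
2.60159819274,-1.18467034499,-1.02953353406,-0.0949288458732,-0.0343336712258
-1.64795279227,3.62288824671,1.52511961914,0.729644562724,0.0269718403801
-3.63333194331,1.2104833481,-0.308652974032,0.336248715811,0.0491085194757
-0.392281310177,0.101541306642,0.465403461213,-0.472666032855,-0.0124134918668
-2.71696242706,0.0885498956286,-1.15374818878,-0.737236813754,0.0473180335077
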