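0.987442841273,0.157626211333,0.660928606949,-0.425271889586,-0.91101790933,-0.386735638485,0.785459022106,-2.90224386902,1.330651380162,-0.004835912315,-2.306969407778,-2.13489872915
0.254322974687,-2.119939547637,2.109604034118,-0.499527804521,-0.464817149289,0.351286844968,2.119206427801,-2.556699121211,1.083106856588,0.175504858248,-2.407198356713,-0.876478817837
-0.908055767114,0.54150507402,-0.972886225485,-0.315436418578,-0.545833052421,-0.138989531209,-1.019656868738,1.591190015867,-0.503015252993,0.097589869903,0.776492139457,0.568432142639
1.053798227049,-2.02479609337,0.422997542543,-1.11777231772,-1.987099243298,0.255189823708,2.623373127834,-2.386613304525,-0.718726925703,0.443887030372,-3.706014472883,-0.449857065725
-0.337393999011,-2.607093873912,2.094597242547,-0.257177040947,0.182839025217,0.639565499723,1.987284526671,-1.085717532686,0.374620944106,0.227285711133,-1.238093402863,0.429311512104
1.023956851094,1.401046382699,-1.196935061175,0.705648572667,0.676647683156,-0.214125471118,-0.717681017714,0.473262043234,-0.769705175416,-0.27984836771,0.968099818522,0.1058211455
1.365153773015,-1.737898832574,0.552353744175,-0.906577691641,-1.70950379775,0.179732058923,2.551806792679,-2.796497622821,-0.431821931242,0.313201600993,-3.627842968566,-0.771530867245
-1.108484463001,-0.367623958042,1.438711758821,0.024547146483,0.574496355576,0.054133615641,-0.279005271808,-0.234315844531,1.651008559263,-0.055508023898,0.457996049861,-0.491864627937
-0.78942946651,1.061397223031,-0.421002511669,0.876032522443,1.585913443277,-0.034700553832,-1.628238678663,2.214488983521,-0.058220059653,-0.25104760133,2.879912879617,1.008423649907
0.309565910655,-1.239582005685,-1.274437187952,-1.45316568039,-2.70459198075,0.106238289771,1.389112246887,-0.262494495896,-1.979696046519,0.581612972045,-2.743867565745,0.528915891396
-0.624453701371,-0.645450940003,-0.732909621283,-1.078760607177,-1.812814648489,0.062968672061,0.293473039054,0.435162233107,-0.789470299975,0.42379934567,-1.298497872315,0.294912340593
-0.575635916656,-0.865363433068,0.065988300922,-0.077267772925,0.154741665775,0.327771996054,0.248249305158,1.116688109706,-0.769735687316,0.173445930262,0.492021719129,1.16305523334
0.975706892911,2.900927999063,-1.048887114864,0.555079310632,0.190343965017,-0.937781497093,-1.691401450156,-0.908146689445,1.101030435129,-0.396087065981,0.503539816686,-1.971613968569
-0.169051782248,1.89877861474,-0.133482479334,0.776692749926,1.248674282449,-0.423045894335,-1.749670727309,0.524046551897,1.155469722096,-0.427901607859,1.967543071399,-0.725381200117
0.038634548834,0.23755320214,1.930156784868,1.310642151257,2.548913521269,0.122896327793,-0.243364031815,-0.66587359041,1.811508961945,-0.451670118823,1.74104526732,-0.530078272311
0.297057857035,1.045663938137,-0.553975372861,-0.07968978857,-0.349473413095,-0.411199611199,-0.579235184886,-0.423068048311,0.391013310656,-0.06477126197,-0.216406229376,-0.873047854508
0.037938790075,-0.851696902886,1.384320113248,0.470318434893,1.217256541306,0.363958867126,0.696083850778,-0.523303471249,0.574903790644,-0.121285452348,0.339345403407,0.185705889857
0.218637995127,-0.143775102806,-1.830332154606,-1.110649030993,-2.272966574037,-0.123816612487,0.36666651173,0.415252678389,-1.785251397719,0.409435296747,-1.690113368261,0.407814051988
-0.764746749756,-1.096823127968,1.245370822893,-0.414315229266,-0.220323685372,0.146973340862,0.584067678987,-0.597061092325,0.913572702127,0.117373364519,-0.659207795237,-0.261565832011
-0.455950851382,1.008644992931,-1.92707417259,-0.770157620683,-1.664251685297,-0.397756456601,-1.045347432425,1.280907732206,-0.960504664057,0.202035425814,-0.180537941061,0.158339593504
-0.861516079827,-1.472924723687,1.899351164461,0.003925027223,0.671515283139,0.380575814266,0.724738897144,-0.527472833925,1.181412905518,0.041694943162,-0.02298377972,0.027742711492
-0.177419191417,0.11764597034,-0.774777138972,0.229345882296,0.342181335945,0.157926724778,-0.374120631266,1.520252871267,-1.10358568602,-0.027041992023,1.112189020673,1.185202962969
-0.020589868755,-0.037184315902,1.115802042024,0.026578256851,0.152242380976,-0.131714147807,0.222850384704,-1.394869185474,1.434697210064,-0.07200260866,-0.556303688156,-1.125450157394
-0.147813769443,-0.356076792503,-0.590026262416,-0.600239709982,-1.060783006436,0.012722908754,0.258337380826,0.268263780995,-0.718811525168,0.235291700007,-0.799159603147,0.309498757726
1.08266754605,-1.786109426267,-0.185864082054,-1.147539358693,-2.245164869076,0.243706348495,2.371678303307,-1.921530148004,-1.20188911009,0.477651369618,-3.559813046478,-0.193711212924
0.04926159964,0.949278203462,0.36316397116,0.066902864443,-0.033926440452,-0.429191890178,-0.550205816022,-1.088844996474,1.454596918009,-0.163749292374,-0.258599269136,-1.43600165901
-0.681757561026,-0.319140856953,1.742372377172,0.408259958233,1.196641523875,0.071368965685,-0.08659241438,-0.622358357224,1.824123966658,-0.169295301139,0.637089499799,-0.594117115198
0.093902094844,-2.92610407119,1.752481983437,-0.543536651644,-0.4036042292,0.763526278022,2.586193523861,-1.365396483549,-0.300520757929,0.360456109598,-2.034936887368,0.609982237242
-0.85726791788,-1.081033048764,0.958884769972,-0.584852312287,-0.555976981406,0.182480143999,0.51511515645,-0.373011718475,0.700750900577,0.226316885639,-0.793217941167,-0.096940361744
0.908263004374,0.098317886458,-0.615076156719,-0.577696925632,-1.303628404239,-0.226665300913,0.573858172444,-1.235178043752,-0.346127007823,0.146996554571,-1.742435348655,-0.78545680447
-0.261403121273,-0.671230819901,-0.220921715282,-0.006873812602,0.09120281579,0.309353413863,0.272227884827,0.971727876958,-0.941496828034,0.088360978681,0.411574391864,1.136954414159
-0.013693833355,0.662319252259,-0.99522485747,-0.861778656578,-1.759297414369,-0.430111725997,-0.31427172511,-0.430718321606,-0.020566953738,0.189612475413,-1.392239217238,-0.899838379099
0.502366088584,-0.393088882136,0.765543763919,0.022363112168,0.072035220071,0.011212957589,0.757085380523,-1.333969553004,0.539041997911,-0.059431140335,-0.874474280877,-0.624386627468
-1.03168188333,-1.523396948178,1.638922919396,-0.114738154643,0.456088719648,0.463271950294,0.645281455696,0.00685524512,0.795286165854,0.09258043681,0.08265109514,0.411548664134
-0.27442432839,0.596385479389,-1.771093121563,0.157505079601,0.077639740054,0.127994279142,-0.942296975006,2.64583503127,-1.972413452665,0.093097500037,1.625480229002,1.760781750991
-0.013830037174,1.273462980353,-1.094217899882,-0.074691854266,-0.439489922245,-0.36261783481,-1.082468070722,0.572218411747,-0.15475742414,-0.081609886787,0.387776966227,-0.316254599919
-0.016659098925,-2.199566630908,2.872999384834,0.525405298595,1.584432918617,0.658135127934,1.817046009785,-1.487384456784,1.196171873409,-0.04031928207,-0.277425773929,0.092263362103
0.578435747617,-1.776829832715,1.680289855504,-0.365263325841,-0.457004436824,0.277195775043,2.033769421407,-2.471747897434,0.77662861997,0.206787309475,-2.315750452587,-0.80986530435
-0.394793055952,-0.851073684491,0.562526061812,-0.428602624043,-0.45991271828,0.140658738821,0.572760531016,-0.374816449974,0.275186675639,0.160208799889,-0.731609667328,-0.021108541181
0.063379346986,-0.944168846181,0.857163120957,-0.801671433809,-1.309741287571,-0.054998109964,1.099896178402,-1.938635369281,0.855944628872,0.278202445215,-2.309158229829,-1.176601244979
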