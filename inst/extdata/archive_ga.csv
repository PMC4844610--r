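"AgRP.LepRB","AgRP.GHSR","AgRP.FHT1BR","POMC.LepRB","POMC.Y1R","POMC.GABAR","POMC.FHT2CR","NGABA.LepRB","OXT.MCR","OXT.GABAR","OXT.Y1R","OXT.MCHR","MCH.GLUR","OX.GLUR","OX.GHSR","OX.GalR","OX.AgRPR","OX.POMCR","LHGal.LepRB","NT.LepRB","NTSCA.LepRB","NTSCA.GHSR","NTSCA.OXR","NTSCA.OXTR","NTSCA.CCKR","NTSGLP1.LepRB","NTSGLP1.AR","VTA.LepRB","VTA.GHSR","VTA.OXR","VTA.NTR","VTA.GLP1R","NAc.DR","NAc.Y1R","NAc.MCHR","NAc.GLP1R","FI.NAcR","FI.NTSCAR","AgRP.Bias","POMC.Bias","NGABA.Bias","OXT.Bias","MCH.Bias","OX.Bias","LHGal.Bias","NT.Bias","NTSCA.Bias","NTSGLP1.Bias","VTA.Bias","NAc.Bias","FI.Bias","error","distance"
0.803174052114991,2.12008863353695,0.764496000940628,0.563827279268413,0.390398487297296,1.2445176658097,5,0.519985731369935,3.60576014019226,0.241136142344334,0.155633934541909,0.973903257112377,0.058256171786622,0.557670135323099,0.374299550617582,1.74048937089353,2.2510391882366,0.428377968157209,0.884443101029535,0.325370145716237,4.11798094904581,0.00249837468521226,2.67104148908826,0.350791521520666,0.426699560267949,0.3562071430051,1.85144255240708,0.359456657865083,0,4.72799282424855,2.3462023322366,1.28161301856933,2.62316768690052,3.96354301297006,2.2331972460042,1.80467911403506,0.871351546672087,0.140940308008608,1.86307757550305,4.32431285139075,-2.82998499436919,-0.118525045544899,-2.19238740087752,1.93434728611123,3.41346131982553,2.60672556465855,-2.66387340280531,-4.0101691911854,-2.23369667871416,-4.63651461722507,2.52329829298885,0,16.0961179676707
0.787342419411149,4.21873863917483,0.779114489630318,0.400127673320918,0.249611568940551,1.63912050763388,4.09277981268161,2.60229183224891,2.16821918730154,0.194177786661335,0.131271108924985,0.742983577346586,2.98537354500141,0.938416576611196,0.104241312425622,0.241171055445042,4.97805083675045,4.80939030088411,1.44559246830588,1.4285099910199,1.41042895014528,1.69096225795304,1.6122614043398,0.0357106214240467,1.94476085221492,0.958286034662226,0.315347324941963,4.9510280514255,2.4400754996568,0.0221920147910364,1.33641571751545,1.21487882839563,1.27565824301566,0.721089768541035,0,2.94901058256885,2.95834037645928,1.4374104376352,-0.584713508533268,4.85800509373639,0.408118825861816,1.93601420789936,-0.95050389202309,2.72509800494917,-0.655688453080243,0.546527577836058,2.69144317809966,-2.74601605479512,1.11818172185986,-1.04030383999389,4.98944407531534,0,16.1007820243755
0.854309382629196,1.99518664766342,0.833617017954432,0.647757788247279,0.611008581426709,0.594994654641562,4.38053865289903,1.83248497207587,1.51202422587737,0.105426640518248,0.160491874512157,0.384668821330208,3.39644703657886,1.05664873118667,0.193610643282644,0.247655041867996,2.46221661435835,1.11700099954441,0.989298744149622,3.80980840175384,2.51245530299156,0.372465434763653,1.69147474816542,0.405105144218604,0.492107769853777,0.868367691518029,0.901093584860323,1.94948300998118,4.0291445374025,0.439146125111777,0.285816034884754,0.196358711515945,3.84532865633134,3.03880147588651,0.151727552146174,2.18744786351524,2.0662536311369,0.38880677868113,2.12814378469339,4.28864811224666,2.56828031965561,2.45614650883983,2.07246322305542,-2.05410721599536,3.45894443281784,4.9782089674591,2.68714895948864,-3.09600660626485,-2.41341374634614,2.86028136184007,5,0,16.3899439602483
0.727529829314174,1.0854125216308,0.845129371302125,0.699723620623122,1.93911204925138,0.0216343956461857,4.87700782843883,0.20824349401343,2.21368598536439,0.231586482785556,0.0973217604170858,0.219395676135265,1.54400863698529,0.558824860333362,1.77667811368634,1.41480949085602,3.66663866506533,1.9508978469054,2.9915707923268,0.993460032444416,4.93313191026118,0.2690812973488,2.17932303123033,0.39016580054921,4.52893948065329,3.33603265317641,2.3612924884051,0.276045851730357,0.165463290183586,0.245604605086947,1.16392096164019,0.0240832706211785,2.10581101556528,3.10545920365812,2.51744348763382,0.511726939253245,1.29521107666653,0.170888419064631,2.78352059400809,4.32969942072732,0.228652358146371,0.864989860106957,-1.04481196055696,-2.23764597838358,0.387512753202542,-0.284958908171032,4.29938273551505,-2.71404336922712,3.73989363193208,-4.04846063274005,4.38104607261244,0,16.4325574874183
0.919676806102071,4.9743152747308,0.971087747301427,0.43072182033095,0.253308181310484,0.570487884143625,4.26081007035416,2.85333675560105,2.06232598593558,0.475713860414558,0.355216368501008,0.203050167289352,0,0.0684714384168189,0.235366812905894,1.3023665574107,5,2.6267228910818,0.723644598660618,4.19063739913715,4.95800903084845,0.18984342873261,4.56243005646506,0.503315160617057,2.16465849185545,0,0.566603268518175,0.514606756383061,1.1775140811108,1.05323224370058,1.50930914737848,0.161703609806755,0.00955553847978035,1.96754709092334,0.787001129555224,2.1783203272716,0.456451924179427,0.181104466947763,-0.532581158034831,4.87792087694131,4.84475644431941,1.20568740721983,0.458491183126952,-4.43064961741515,0.158982994818389,1.54966724950085,0.587730714553047,-1.70309024000494,0.0199858349143041,-4.91688244820833,3.65983367462929,0,16.9444511664721
0.711108621523193,3.21331138142151,1.1955208176731,1.45138684540665,0.326238246816847,0.378219352679323,3.80799719097517,1.63015155219853,3.42364173614225,0.300314550460086,0.107962245097544,3.03934505189662,0,2.13886992016609,0.00131108093193247,2.50339413613627,5,1.88334889465483,4.42033929323984,0.404492952444506,2.78582089180043,2.01013701547867,4.72217176633643,0.0742049725862906,0.198902128766226,5,3.45023638097889,0.338605247807437,0.181317599573331,2.8782902804693,2.10229882863111,0.895816056583833,3.05722405120456,4.57271555705819,4.59374609952079,2.08557040635071,1.3325261210062,0.818870264711866,0.995368083473654,1.78738651942357,0.218058209078177,0.542493724445438,-0.515933844977524,2.5805164549226,1.57285492361148,3.89233296965322,-0.409123720054885,0.278907107852846,3.65267435778645,-0.255725811638394,3.13802624858416,0,17.5317445416474
0.889156204986098,1.74944989537559,0.948724743706215,0.521045886762489,0.940685339143909,0.221171883260351,4.34600274462992,0.53202782320666,4.96047168243362,0.355726397725422,0.515680725655757,0.413599701213151,2.95037208013774,0,1.75249946322997,4.68850507570709,3.31548076499454,0,0.695705388654385,0.717531983861744,4.86552174434064,0.601953709136814,3.52630890601499,0.294133348366615,0.000203887631621701,2.37735058993559,1.13196501156452,4.75888258962641,0.796202428217974,1.09404987272944,4.4926307366135,0.0826526331722646,0.584128647366162,0.367847168063093,0.570626341481629,1.49036249012711,0.753112336825499,0.123724162610369,2.50606603552965,3.53502620081436,1.53768171187127,4.99043976259991,3.9813009354032,1.86232400150117,2.74857808084591,3.31272080862295,3.33779858247576,-3.19385237523272,3.35544492675955,-4.97631496998456,3.12273091473557,0,18.4070671799785
0.918674244375287,2.80247601384907,1.0677361779647,0.976537088043828,0.651461781391195,0.269943259263867,4.29933395457646,3.85869913625497,2.67286647374329,0.558260605432576,0.399378599195482,2.80095421554052,0,0.783468104155738,1.92717045801063,0.0673025664802964,2.95188657406429,1.38478172449821,4.95737930875042,2.65243655242381,5,4.61668127092352,2.9808744845538,0.41745065605996,1.92018077709345,0.301082363727378,0.907362587201766,0,2.70395773325947,0.821742774007718,2.29440014635735,1.70750131751562,4.09163597753005,0.700689190034137,1.62332490036843,0.934603991557286,1.77149484721063,0.254956148535003,1.47519157378027,3.08009571155982,4.70914730766535,1.05117183880675,-2.61658789302782,-4.53395827616465,0.279307837774696,4.35837199767473,-0.76925033580854,2.03504348776482,-4.99806114354209,-5,4.24275249711303,0,18.9978705686329
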