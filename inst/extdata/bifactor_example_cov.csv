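3.1010622589337262,1.8474626668956518,0.93190648099221152,1.9248497110355056,2.1793857847697198,0.91057013065517056,1.9534085961982097,0.86238804048695406,1.1592536957940829,1.3253898563483555,1.8377327251122033,0.78801714629299535,0.97537929416442715,0.34960838827641777,-0.010612203214924662
1.8474626668956518,2.8601834376119482,0.16622506013946461,2.0129599615241456,2.2151865653364435,0.25825495983921792,1.4632786123096859,0.25105271489782688,0.90987477297176378,0.97559887051026972,1.5521794284554491,0.099077782977667131,0.82577965245189278,-0.17167230083161478,-0.40491769984743697
0.93190648099221152,0.16622506013946461,3.2234802215044973,-0.034254153474114403,0.13846410381352131,1.9069937111007587,1.5712751233828166,1.7881761456870231,0.8175003871342873,1.1138796349565723,0.99173868713048441,1.9951212538127692,0.52094023914479637,1.4826957879450915,1.0915389478818533
1.9248497110355056,2.0129599615241456,-0.034254153474114403,3.1990444941689864,2.4028865232872616,0.096815526840888677,1.4437960602187447,0.10047899281483874,0.91322693243311059,0.95618371789943535,1.5969558324253992,-0.085358051421334652,0.8502486946810297,-0.33100967176058582,-0.5475086918770149
2.1793857847697198,2.2151865653364435,0.13846410381352131,2.4028865232872616,3.6395416313925151,0.25680253546413945,1.7037384536404654,0.25140851399074965,1.0636905072916292,1.1341335326581168,1.8254277024112979,0.064490912703123349,0.97133113542271199,-0.24478065236592378,-0.51256583036648329
0.91057013065517056,0.25825495983921792,1.9069937111007587,0.096815526840888677,0.25680253546413945,3.7298277334676881,0.40451044991159524,2.5466298100529561,-0.0087041360988547173,0.37781129447507167,0.37110358594390458,2.2039700168644458,0.18989543008810289,1.7561462387181512,1.4271101030790847
1.9534085961982097,1.4632786123096859,1.5712751233828166,1.4437960602187447,1.7037384536404654,0.40451044991159524,4.0615938421385867,0.39870003854363034,1.9170125092916019,2.0357053738695878,2.3179864602806477,0.90467887365006994, 1.230583234598942,0.36738643743628158,-0.075781509211603426
0.86238804048695406,0.25105271489782688,1.7881761456870231,0.10047899281483874,0.25140851399074965,2.5466298100529561,0.39870003854363034,3.3758779049422394,0.0055155544361953487,0.36652862018369992,0.36228462224362001,2.0601713978925544,0.18569874458502933,1.6390534815321836,1.3292953358668231
1.1592536957940829,0.90987477297176378,0.8175003871342873,0.91322693243311059,1.0636905072916292,-0.0087041360988547173,1.9170125092916019,0.0055155544361953487,2.2259802413124925,1.2639991943991757,1.4450565673255131,0.36242007110292118,0.76785497416983017,0.062883062064580469,-0.18812865571205767
1.3253898563483555,0.97559887051026972,1.1138796349565723,0.95618371789943535,1.1341335326581168,0.37781129447507167,2.0357053738695878,0.36652862018369992,1.2639991943991757,2.3580014555746467,1.5439053224506771,0.6863080916821156,0.8193460357731267,0.31372785268326886,0.0080577718948187677
1.8377327251122033,1.5521794284554491,0.99173868713048441,1.5969558324253992,1.8254277024112979,0.37110358594390458,2.3179864602806477,0.36228462224362001,1.4450565673255131,1.5439053224506771,4.3830751102401422,-0.67482574956425001,1.8029190800288495,-1.1084278755788062,-1.505154323430324
0.78801714629299535,0.099077782977667131,1.9951212538127692,-0.085358051421334652,0.064490912703123349,2.2039700168644458,0.90467887365006994,2.0601713978925544,0.36242007110292118,0.6863080916821156,-0.67482574956425001,4.1135271959509154,-0.36992739887752124,2.6766006173520878,2.3823665734992288
0.97537929416442715,0.82577965245189278,0.52094023914479637,0.8502486946810297,0.97133113542271199,0.18989543008810289, 1.230583234598942,0.18569874458502933,0.76785497416983017,0.8193460357731267,1.8029190800288495,-0.36992739887752124,1.9608529280225349,-0.59919473423990555,-0.8093288330348597
0.34960838827641777,-0.17167230083161478,1.4826957879450915,-0.33100967176058582,-0.24478065236592378,1.7561462387181512,0.36738643743628158,1.6390534815321836,0.062883062064580469,0.31372785268326886,-1.1084278755788062,2.6766006173520878,-0.59919473423990555,3.3872162597451929,2.2094336014940237
-0.010612203214924662,-0.40491769984743697,1.0915389478818533,-0.5475086918770149,-0.51256583036648329,1.4271101030790847,-0.075781509211603426,1.3292953358668231,-0.18812865571205767,0.0080577718948187677,-1.505154323430324,2.3823665734992288,-0.8093288330348597,2.2094336014940237,3.1249713672497488
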