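{"J":[15],"G":[3],"seed":[20260921],"N_nominal":[1000],"note":["population covariance of a generated exact bi-factor model (generator defaults)"],"loadings":[[1.1242864120286,-0.914900170871988,0,0],[0.68214538693428,-1.18104238226078,0,0],[1.34786780970171,0.637755900854245,0,0],[0.613400915171951,-1.35010511125438,0,0],[0.77766834711656,-1.42645489703864,0,0],[1.19241538876668,0,-1.14366659219377,0],[1.37595050549135,0,1.08090427354909,0],[1.12091722898185,0,-1.05802763230167,0],[0.762621133122593,0,0.80273859295994,0],[0.955993445590138,0,0.666391767328605,0],[1.0662409029901,0,0,-1.4987346152775],[1.19368143030442,0,0,1.29948137304746],[0.563363135559484,0,0,-0.802168875932693],[0.809914760990068,0,0,1.31577138579451],[0.508608816657215,0,0,1.36612167791463]],"beta":[-0.450838456396013,0.578515227418393,-0.454456801060587],"psi":[1,1,1,1,1,1,1,1,1,1,1,1,1,1,1],"clusters":{"group_1":[1,2,3,4,5],"group_2":[6,7,8,9,10],"group_3":[11,12,13,14,15]}}
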