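[*]n1c2ccccc2c2ccccc21 carbazol-9-yl
[*]n1c2ccc(C)cc2c2cc(C)ccc21 3,6-dimethylcarbazol-9-yl
[*]n1c2ccc(C(C)(C)C)cc2c2cc(C(C)(C)C)ccc21 3,6-di-tert-butylcarbazol-9-yl
[*]n1c2ccc(OC)cc2c2cc(OC)ccc21 3,6-dimethoxycarbazol-9-yl
[*]n1c2ccc(F)cc2c2cc(F)ccc21 3,6-difluorocarbazol-9-yl
[*]n1c2ccccc2c2cc(-n3c4ccccc4c4ccccc43)ccc21 3-(carbazol-9-yl)carbazol-9-yl
[*]N1c2ccccc2Oc2ccccc21 phenoxazin-10-yl
[*]N1c2ccccc2Sc2ccccc21 phenothiazin-10-yl
[*]N1c2ccccc2C(C)(C)c2ccccc21 9,9-dimethylacridin-10-yl
[*]N1c2ccccc2N(c2ccccc2)c2ccccc21 5-phenyl-5,10-dihydrophenazin-10-yl
[*]N(c1ccccc1)c1ccccc1 diphenylamino
[*]N(c1ccc(C)cc1)c1ccc(C)cc1 di-p-tolylamino
[*]N(c1ccc(OC)cc1)c1ccc(OC)cc1 bis(4-methoxyphenyl)amino
[*]N(C)c1ccccc1 N-methylanilino
[*]N(c1ccccc1)c1ccc(OC)cc1 (4-methoxyphenyl)(phenyl)amino
[*]N(c1ccccc1)c1cccc2ccccc12 naphthalen-1-yl(phenyl)amino
[*]c1ccc(N(c2ccccc2)c2ccccc2)cc1 4-(diphenylamino)phenyl
[*]c1cccc(N(c2ccccc2)c2ccccc2)c1 3-(diphenylamino)phenyl
[*]c1ccc(-n2c3ccccc3c3ccccc32)cc1 4-(carbazol-9-yl)phenyl
[*]c1cccc(-n2c3ccccc3c3ccccc32)c1 3-(carbazol-9-yl)phenyl
[*]c1ccc(N2c3ccccc3Oc3ccccc32)cc1 4-(phenoxazin-10-yl)phenyl
[*]c1ccc(N2c3ccccc3Sc3ccccc32)cc1 4-(phenothiazin-10-yl)phenyl
[*]c1ccc(N2c3ccccc3C(C)(C)c3ccccc32)cc1 4-(9,9-dimethylacridin-10-yl)phenyl
[*]c1ccc(N(C)C)cc1 4-(dimethylamino)phenyl
[*]c1ccc(OC)cc1 4-methoxyphenyl
[*]c1cc(OC)cc(OC)c1 3,5-dimethoxyphenyl
[*]c1ccc2c(c1)oc1ccccc12 dibenzofuran-2-yl
[*]c1ccc2c(c1)sc1ccccc12 dibenzothiophen-2-yl
[*]c1ccc2c(c1)C(C)(C)c1ccccc12 9,9-dimethylfluoren-2-yl
[*]c1ccc(-c2ccccc2)cc1 biphenyl-4-yl
[*]c1ccccc1 phenyl
[*]c1ccc(C)cc1 p-tolyl
[*]c1ccc2ccccc2c1 naphthalen-2-yl
[*]c1ccc(-c2ccc(N(c3ccccc3)c3ccccc3)cc2)cc1 4p-(diphenylamino)biphenyl-4-yl
[*]c1ccc2c(c1)ccc1ccccc12 phenanthren-3-yl
[*]c1cccc2c1ccc1ccccc12 phenanthren-4-yl
[*]c1cc(C)cc(C)c1 3,5-dimethylphenyl
[*]c1ccc(C(C)(C)C)cc1 4-tert-butylphenyl
[*]c1cccc(-c2ccccc2)c1 biphenyl-3-yl
[*]c1ccc(-c2ccc(-c3ccccc3)cc2)cc1 p-terphenyl-4-yl
[*]c1ccc2c(c1)C(C)(C)c1cc(C)ccc12 7,9,9-trimethylfluoren-2-yl
[*]c1cccc2ccccc12 naphthalen-1-yl
[*]c1ccc(-c2ccc3ccccc3c2)cc1 4-(naphthalen-2-yl)phenyl
[*]c1ccc2c(c1)c1ccccc1c1ccccc12 triphenylene-2-yl
[*]c1ccc(-c2cccc(-c3ccccc3)c2)cc1 m-terphenyl-4-yl
[*]c1ccc2c(c1)C(C)(C)c1ccc(-c3ccccc3)cc12 7-phenyl-9,9-dimethylfluoren-2-yl
[*]c1cc(C)c(C)cc1C 3,4,5-trimethylphenyl? drop
[*]c1ccc(CC)cc1 4-ethylphenyl
[*]c1ccc2cc3ccccc3cc2c1 anthracen-2-yl
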