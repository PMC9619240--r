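[*]c1ccc(C#N)cc1 4-cyanophenyl
[*]c1cccc(C#N)c1 3-cyanophenyl
[*]c1ccc(C#N)c(C#N)c1 3,4-dicyanophenyl
[*]c1cc(C#N)cc(C#N)c1 3,5-dicyanophenyl
[*]c1ccc(C#N)c(F)c1 2-fluoro-4-cyanophenyl
[*]c1c(F)c(F)c(C#N)c(F)c1F tetrafluoro-4-cyanophenyl
[*]c1cc(C#N)c(F)cc1F cyanodifluorophenyl
[*]c1cc(C#N)cc(F)c1 3-cyano-5-fluorophenyl
[*]c1nc(-c2ccccc2)nc(-c2ccccc2)n1 4,6-diphenyl-1,3,5-triazin-2-yl
[*]c1nc(C)nc(C)n1 4,6-dimethyl-1,3,5-triazin-2-yl
[*]c1ncncn1 1,3,5-triazin-2-yl
[*]c1ccncn1 pyrimidin-4-yl
[*]c1ncccn1 pyrimidin-2-yl
[*]c1ccnnc1 pyridazin-4-yl
[*]c1cnccn1 pyrazin-2-yl
[*]c1ccncc1 pyridin-4-yl
[*]c1cccnc1 pyridin-3-yl
[*]c1cnc(C#N)cn1 5-cyanopyrazin-2-yl
[*]c1ccc(C#N)nc1 6-cyanopyridin-3-yl
[*]c1ccc(-c2ccncc2)cc1 4-(pyridin-4-yl)phenyl
[*]c1ccc(S(C)(=O)=O)cc1 4-(methylsulfonyl)phenyl
[*]c1ccc(S(=O)(=O)c2ccccc2)cc1 4-(phenylsulfonyl)phenyl
[*]c1ccc(S(=O)(=O)C(F)(F)F)cc1 4-(trifluoromethylsulfonyl)phenyl
[*]c1ccc2c(c1)S(=O)(=O)c1ccccc12 dibenzothiophene-S,S-dioxid-2-yl
[*]c1ccc(C(=O)c2ccccc2)cc1 4-benzoylphenyl
[*]C(=O)c1ccccc1 benzoyl
[*]c1ccc(C(C)=O)cc1 4-acetylphenyl
[*]c1ccc2c(c1)C(=O)c1ccccc1C2=O anthraquinon-2-yl
[*]c1ccc(C(F)(F)F)cc1 4-(trifluoromethyl)phenyl
[*]c1cc(C(F)(F)F)cc(C(F)(F)F)c1 3,5-bis(trifluoromethyl)phenyl
[*]c1ccc(F)cc1 4-fluorophenyl
[*]c1cc(F)cc(F)c1 3,5-difluorophenyl
[*]c1c(F)cc(F)cc1F 2,4,6-trifluorophenyl
[*]c1ccc2nccnc2c1 quinoxalin-6-yl
[*]c1cnc2ccccc2n1 quinoxalin-2-yl
[*]c1cccc2cccnc12 quinolin-8-yl
[*]c1ccc2ncccc2c1 quinolin-6-yl
[*]c1nnc(-c2ccccc2)o1 5-phenyl-1,3,4-oxadiazol-2-yl
[*]c1ccc(-c2nnc(-c3ccccc3)o2)cc1 4-(5-phenyl-1,3,4-oxadiazol-2-yl)phenyl
[*]c1nc2ccccc2o1 benzoxazol-2-yl
[*]c1nc2ccccc2s1 benzothiazol-2-yl
[*]c1nc2ccccc2n1-c1ccccc1 1-phenylbenzimidazol-2-yl
[*]c1ccc(-c2nc3ccccc3o2)cc1 4-(benzoxazol-2-yl)phenyl
[*]c1ccc(N2C(=O)c3ccccc3C2=O)cc1 4-phthalimidophenyl
[*]c1ccc(P(=O)(c2ccccc2)c2ccccc2)cc1 4-(diphenylphosphoryl)phenyl
[*]c1ccc(-c2ccc(C#N)cc2)cc1 4p-cyanobiphenyl-4-yl
[*]c1ccc(S(=O)(=O)c2ccc(C#N)cc2)cc1 4-(4-cyanophenylsulfonyl)phenyl
[*]c1cc(F)c(C#N)c(F)c1 3,5-difluoro-4-cyanophenyl
[*]c1ccc(F)c(F)c1 3,4-difluorophenyl
[*]c1ccc(S(=O)(=O)c2ccc(C)cc2)cc1 4-tosylphenyl
[*]c1ccc(C(=O)c2ccc(F)cc2)cc1 4-(4-fluorobenzoyl)phenyl
[*]C(=O)c1ccc(F)cc1 4-fluorobenzoyl
[*]c1ccc(C(=O)C(C)(C)C)cc1 4-pivaloylphenyl
[*]c1ccc2c(c1)C(=O)c1ccccc12 9-fluorenon-2-yl
[*]c1ccc2c(c1)Oc1ccccc1C2=O xanthon-2-yl
[*]c1ccc2S(=O)(=O)c3ccccc3c2c1 dibenzothiophene-S,S-dioxid-3-yl
[*]c1cccc(S(=O)(=O)c2ccccc2)c1 3-(phenylsulfonyl)phenyl
[*]c1cccc(C(F)(F)F)c1 3-(trifluoromethyl)phenyl
[*]c1ccc(C(=O)c2ccc(C)cc2)cc1 4-(4-methylbenzoyl)phenyl
[*]C(=O)c1ccc(C(C)(C)C)cc1 4-tert-butylbenzoyl
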