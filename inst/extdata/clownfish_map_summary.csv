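group,size_cM,n_loci,mean_distance_cM
abLG1,203.2357744,147,1.392025852
abLG2,260.8122798,176,1.490355885
abLG3,115.5290105,88,1.327919661
abLG4,212.7948591,169,1.266636066
abLG5,206.2664111,149,1.393691966
abLG6,170.0938091,116,1.479076601
abLG7,151.9575601,139,1.101141748
abLG8,169.6410226,118,1.449923279
abLG9,224.6401694,173,1.306047496
abLG10,235.5013328,167,1.418682728
abLG11,152.1028933,112,1.370296336
abLG12,237.9905629,156,1.535422987
abLG13,154.7149275,124,1.257844939
abLG14,188.8340065,113,1.686017915
abLG15,183.0451833,155,1.188605087
abLG16,203.6771745,146,1.404670169
abLG17,143.7544374,110,1.318848049
abLG18,166.2292002,124,1.351456912
abLG19,161.4636246,137,1.187232534
abLG20,148.370463,88,1.705407621
abLG21,228.0358364,179,1.281100204
abLG22,87.79384775,65,1.384601096
abLG23,117.382178,79,1.504899719
abLG24,170.8397613,116,1.485563142
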