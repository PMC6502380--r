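sex,strain,sea_winters,families,n_individuals,n_kype_height
male,Mowi,1,5,14,12
male,Mowi,2,4,16,12
male,Mowi,3,4,14,14
male,HybridFM,1,6,95,91
male,HybridFM,2,5,8,7
male,HybridFM,3,5,13,11
male,HybridMF,1,7,91,85
male,HybridMF,2,6,18,11
male,HybridMF,3,4,4,4
male,Arna,1,6,63,62
male,Arna,2,4,11,10
male,Arna,3,3,7,6
male,Figgjo,1,6,64,61
male,Figgjo,2,6,8,6
male,Figgjo,3,0,0,0
male,Vosso,1,7,70,67
male,Vosso,2,6,20,12
male,Vosso,3,5,12,9
female,Mowi,2,0,0,NA
female,HybridMF,2,7,32,NA
female,HybridFM,2,5,14,NA
female,Arna,2,3,13,NA
female,Figgjo,2,4,11,NA
female,Vosso,2,2,4,NA
female,unknown,2,NA,3,NA
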