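species	cnl	tnl	rnl	total_nbs	predicted_proteins	genome_size_mb
Aquilegia caerulea	231	1	1	233	41063	306
Nymphaea colorata	234	115	11	360	31589	409
Akebia trifoliata	50	19	4	73	24138	645
Amborella trichopoda	84	25	1	110	31494	706
Arabidopsis thaliana	55	94	NA	149	38311	125
Carica papaya	33	20	1	54	24742	372
Populus trichocarpa	236	123	NA	359	41444	410
Vitis vinifera	241	111	NA	352	29585	505
Solanum lycopersicum	222	31	2	255	34727	739
Oryza sativa	535	0	NA	535	37544	389
Dioscorea rotundata	166	0	1	167	26198	594
Setaria italica	96	0	NA	96	35844	406
Triticum aestivum	2148	5	3	2151	107891	15770
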