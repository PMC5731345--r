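##gff-version 3
##sequence-region circuit_synthetic 1 5761
circuit_synthetic	circuitseq	scar	101	120	.	+	.	Name=scar01
circuit_synthetic	circuitseq	promoter	121	155	.	+	.	Name=P_Tac;tss= 155
circuit_synthetic	circuitseq	promoter	156	190	.	+	.	Name=P_Tet1;tss= 190
circuit_synthetic	circuitseq	ribozyme	191	265	.	+	.	Name=RiboJ53;cut_site= 231
circuit_synthetic	circuitseq	rbs	266	285	.	+	.	Name=rbs_AmtR
circuit_synthetic	circuitseq	cds	286	985	.	+	.	Name=AmtR
circuit_synthetic	circuitseq	terminator	986	1045	.	+	.	Name=ECK120029600
circuit_synthetic	circuitseq	scar	1046	1065	.	+	.	Name=scar02
circuit_synthetic	circuitseq	promoter	1066	1100	.	+	.	Name=P_BAD1;tss=1100
circuit_synthetic	circuitseq	promoter	1101	1135	.	+	.	Name=P_Tet2;tss=1135
circuit_synthetic	circuitseq	ribozyme	1136	1210	.	+	.	Name=RiboJ10;cut_site=1176
circuit_synthetic	circuitseq	rbs	1211	1230	.	+	.	Name=rbs_LitR
circuit_synthetic	circuitseq	cds	1231	1880	.	+	.	Name=LitR
circuit_synthetic	circuitseq	terminator	1881	1940	.	+	.	Name=L3S2P55
circuit_synthetic	circuitseq	scar	1941	1960	.	+	.	Name=scar03
circuit_synthetic	circuitseq	promoter	1961	1995	.	+	.	Name=P_BAD2;tss=1995
circuit_synthetic	circuitseq	ribozyme	1996	2070	.	+	.	Name=RiboJ64;cut_site=2036
circuit_synthetic	circuitseq	rbs	2071	2090	.	+	.	Name=rbs_BM3R1
circuit_synthetic	circuitseq	cds	2091	2540	.	+	.	Name=BM3R1
circuit_synthetic	circuitseq	terminator	2541	2600	.	+	.	Name=L3S2P11
circuit_synthetic	circuitseq	scar	2601	2620	.	+	.	Name=scar04
circuit_synthetic	circuitseq	promoter	2621	2655	.	+	.	Name=P_BM3R1;tss=2655
circuit_synthetic	circuitseq	promoter	2656	2690	.	+	.	Name=P_AmtR;tss=2690
circuit_synthetic	circuitseq	ribozyme	2691	2765	.	+	.	Name=RiboJ54;cut_site=2731
circuit_synthetic	circuitseq	rbs	2766	2785	.	+	.	Name=rbs_SrpR
circuit_synthetic	circuitseq	cds	2786	3485	.	+	.	Name=SrpR
circuit_synthetic	circuitseq	terminator	3486	3545	.	+	.	Name=ECK120033737
circuit_synthetic	circuitseq	scar	3546	3565	.	+	.	Name=scar05
circuit_synthetic	circuitseq	promoter	3566	3600	.	+	.	Name=P_SrpR;tss=3600
circuit_synthetic	circuitseq	promoter	3601	3635	.	+	.	Name=P_LitR;tss=3635
circuit_synthetic	circuitseq	ribozyme	3636	3710	.	+	.	Name=RiboJ;cut_site=3676
circuit_synthetic	circuitseq	rbs	3711	3730	.	+	.	Name=rbs_PhlF
circuit_synthetic	circuitseq	cds	3731	4350	.	+	.	Name=PhlF
circuit_synthetic	circuitseq	terminator	4351	4410	.	+	.	Name=L3S2P24
circuit_synthetic	circuitseq	scar	4411	4430	.	+	.	Name=scar06
circuit_synthetic	circuitseq	promoter	4431	4465	.	+	.	Name=P_PhlF;tss=4465
circuit_synthetic	circuitseq	ribozyme	4466	4540	.	+	.	Name=BydvJ;cut_site=4506
circuit_synthetic	circuitseq	rbs	4541	4560	.	+	.	Name=rbs_yfp
circuit_synthetic	circuitseq	cds	4561	5280	.	+	.	Name=yfp
circuit_synthetic	circuitseq	terminator	5281	5340	.	+	.	Name=L3S2P21
circuit_synthetic	circuitseq	scar	5341	5360	.	+	.	Name=scar07
circuit_synthetic	circuitseq	scar	5361	5380	.	+	.	Name=scar08
circuit_synthetic	circuitseq	scar	5381	5400	.	+	.	Name=scar09
circuit_synthetic	circuitseq	scar	5401	5420	.	+	.	Name=scar10
circuit_synthetic	circuitseq	scar	5421	5440	.	+	.	Name=scar11
circuit_synthetic	circuitseq	scar	5441	5460	.	+	.	Name=scar12
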