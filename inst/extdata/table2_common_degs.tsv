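# Genes differentially expressed in both fruit stages (BR and MR),
# transcribed from the source publication's printed table.
# sl30_start/sl30_end are the printed SL3.0 positions. start/end are the
# coordinates used for region intersection: for the five bold (in-region)
# chromosome-7 genes these are the iTAG4.1 coordinates of the same loci
# taken from the relationships table (Solyc07g049140 is represented in
# iTAG4.1 by its substitute annotation Solyc07g049135); elsewhere the
# printed SL3.0 positions are carried over unchanged.
# in_region = 1 marks rows printed in bold (introgression region of R182).
gene_id	chrom	logFC_BR	logFC_MR	sl30_start	sl30_end	start	end	in_region	annotation
Solyc01g073810	1	-6.154	-2.521	81055373	81056169	81055373	81056169	0	LOW QUALITY: Cysteine/Histidine-rich C1 domain family protein
Solyc01g081250	1	-4.587	-4.299	80365913	80367306	80365913	80367306	0	Glutathione s-transferase, putative
Solyc03g045140	3	10.729	5.813	11633346	11652595	11633346	11652595	0	Cyclopropane-fatty-acyl-phospholipid synthase
Solyc03g096130	3	7.654	5.344	59424648	59428566	59424648	59428566	0	Protein yippee-like
Solyc03g096250	3	4.241	4.959	59662319	59665587	59662319	59665587	0	Protein yippee-like
Solyc05g021163	5	-3.790	-3.507	26616597	26617138	26616597	26617138	0	Ubiquitin-conjugating enzyme 34
Solyc07g048040	7	2.461	3.096	59358115	59359332	59117929	59119147	1	Calcium-dependent lipid-binding domain-containing protein
Solyc07g048100	7	-5.474	-5.426	59411341	59428966	59171269	59183106	1	BRCT domain-containing protein
Solyc07g049140	7	-13.070	-13.219	59495183	59496455	59285823	59287144	1	Metallocarboxypeptidase inhibitor
Solyc07g049200	7	-2.536	-1.398	59621580	59624273	59414636	59417346	1	Coiled-coil domain-containing protein 21, putative isoform 2
Solyc07g049310	7	3.003	2.426	59686834	59695592	59479929	59488648	1	Major facilitator superfamily protein
Solyc07g062600	7	-3.908	-4.307	65419623	65420348	65419623	65420348	0	Acyl-CoA N-acyltransferase with RING/FYVE/PHD-type zinc finger protein
Solyc07g062605	7	-3.745	-4.538	65423519	65426708	65423519	65426708	0	Acyl-CoA N-acyltransferase with RING/FYVE/PHD-type zinc finger protein
Solyc09g074380	9	2.161	1.885	66596363	66601065	66596363	66601065	0	DCD (Development and Cell Death) domain protein
Solyc11g011570	11	5.913	4.566	4638263	4639371	4638263	4639371	0	RING/U-box superfamily protein
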