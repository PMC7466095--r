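# Minimal restriction-enzyme resource for in-silico CAPS design.
# cut_offset = number of bases of the recognition site 5' of the cut
# (0 = blunt/overhang cut immediately before the site's first base).
# Sites restricted to the ACGT alphabet (no degenerate bases).
enzyme	site	cut_offset
MboI	GATC	0
SphI	GCATGC	5
EcoRI	GAATTC	1
HindIII	AAGCTT	1
BamHI	GGATCC	1
XbaI	TCTAGA	1
TaqI	TCGA	1
AluI	AGCT	2
HaeIII	GGCC	2
RsaI	GTAC	2
DraI	TTTAAA	3
HhaI	GCGC	3
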