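# Strain-unique mutations of the DvH-MO lineage vs. the published
# D. vulgaris Hildenborough reference (chromosome NC_002937.3, plasmid
# NC_005863.1). Plasmid rows carry plasmid-local positions.
position	replicon	locus_tag	note	aa_change	ref	alt
268940	chromosome	NA	29 bp upstream of DORF26459	NA	A	T
468337	chromosome	NA	140 bp upstream of DORF27863	NA	C	G
1034706	chromosome	DVU0942	ferric uptake regulator (fur)	K->Q	A	C
1118956	chromosome	DVU1017	ABC transporter, ATP-binding protein/permease protein	A->P	G	C
1213311	chromosome	DVU1107	phage tail tape measure protein	NA	G	A
1884231	chromosome	DVU1819	protein-export membrane protein SecD	P->A	G	C
2099891	chromosome	DVU2020	type I phosphodiesterase/nucleotide pyrophosphatase	NA	G	A
2904348	chromosome	DVU2801	hypothetical protein	V->G	T	G
2918165	chromosome	NA	intergenic, between DVU2815 and DVU2812	NA	C	T
3098151	chromosome	DVU2990	molybdopterin biosynthesis MoeA protein	A->G	C	G
40114	plasmid	DVUA0034	conserved domain protein, molybdopterin/thiamine biosynthesis	P->R	G	C
92886	plasmid	DVUA0070	conserved domain protein, polysaccharide pyruvyl transferase	NA	A	T
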