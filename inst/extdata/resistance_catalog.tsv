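# Published target-site resistance mutations screened by the pipeline.
# Positions are 1-based in the cited reference species' protein and follow
# each source's own numbering convention (never renumbered).
# version: 1
target_gene	reference_species	reference_seq_id	position	wild_type_aa	resistant_aa	insecticide_class
DSC1	Drosophila melanogaster	Dmel_DSC1	1924	D	N	DDT
Ryr	Plutella xylostella	Pxyl_Ryr	1338	E	D	diamide
Ryr	Plutella xylostella	Pxyl_Ryr	4594	Q	L	diamide
Ryr	Plutella xylostella	Pxyl_Ryr	4790	I	M	diamide
Ryr	Plutella xylostella	Pxyl_Ryr	4946	G	E	diamide
RDL	Drosophila melanogaster	Dmel_RDL	302	A	S	cyclodiene/phenylpyrazole
TAR1	Rhipicephalus microplus	Rmic_TAR1	8	T	P	formamidine
TAR1	Rhipicephalus microplus	Rmic_TAR1	22	L	S	formamidine
OctB2R	Rhipicephalus microplus	Rmic_OctB2R	61	I	F	formamidine
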