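gene_id	symbol	exclusive_drg	exclusive_tg
ENSMUSG00000020123	Avpr1a	FALSE	TRUE
ENSMUSG00000038112	AW551984	TRUE	FALSE
ENSMUSG00000063415	Cyp26b1	TRUE	FALSE
ENSMUSG00000029054	Gabrd	FALSE	TRUE
ENSMUSG00000078706	Gm53	TRUE	FALSE
ENSMUSG00000043219	Hoxa6	TRUE	FALSE
ENSMUSG00000038236	Hoxa7	TRUE	FALSE
ENSMUSG00000038227	Hoxa9	TRUE	FALSE
ENSMUSG00000000938	Hoxa10	TRUE	FALSE
ENSMUSG00000048763	Hoxb3	TRUE	FALSE
ENSMUSG00000038700	Hoxb5	TRUE	FALSE
ENSMUSG00000000690	Hoxb6	TRUE	FALSE
ENSMUSG00000038721	Hoxb7	TRUE	FALSE
ENSMUSG00000001661	Hoxc6	TRUE	FALSE
ENSMUSG00000001657	Hoxc8	TRUE	FALSE
ENSMUSG00000036139	Hoxc9	TRUE	FALSE
ENSMUSG00000022484	Hoxc10	TRUE	FALSE
ENSMUSG00000027102	Hoxd8	TRUE	FALSE
ENSMUSG00000043342	Hoxd9	TRUE	FALSE
ENSMUSG00000050368	Hoxd10	TRUE	FALSE
ENSMUSG00000028033	Kcnq5	TRUE	FALSE
ENSMUSG00000049112	Oxtr	FALSE	TRUE
ENSMUSG00000005268	Prlr	TRUE	FALSE
ENSMUSG00000026475	Rgsl6	FALSE	TRUE
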