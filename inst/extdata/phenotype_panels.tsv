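# Published example phenotype panels: per-gene Sanger amplicon counts.
# Note: the published SCID table prints a total of 199 amplicons, but its own
# gene list (shipped verbatim below) sums to 217; the printed total equals the
# sum without AK2 (18). panel_amplicons() sums the gene list, giving 217.
# The same source prints a >60-amplicon break-even while $10/$580 implies 59.
phenotype	gene	amplicons
DOCK8_deficiency	DOCK8	62
MSMD	IFNGR1	8
MSMD	IFNGR2	8
MSMD	IL12RB1	17
MSMD	IL12B	7
MSMD	ISG15	3
MSMD	STAT1	21
MSMD	IRF8	16
MSMD	GATA2	15
MSMD	CYBB	20
HIGM	CD40LG	8
HIGM	CD40	12
HIGM	ICOS	5
HIGM	PIK3CD	18
HIGM	AICDA	5
HIGM	NFKBIA	7
ALPS	FAS	9
ALPS	FASL	4
ALPS	CASP8	10
ALPS	CASP10	11
ALPS	NRAS	4
ALPS	KRAS	5
ALPS	CTLA4	8
ALPS	PIK3CD	18
SCID	CD3D	6
SCID	CD3E	11
SCID	DCLRE1C	29
SCID	ORAI1	6
SCID	ADA	12
SCID	IL2RG	8
SCID	IL7R	14
SCID	NHEJ1	8
SCID	PTPRC	40
SCID	RAG1	7
SCID	RAG2	4
SCID	JAK3	18
SCID	CORO1A	14
SCID	PRKCD	22
SCID	AK2	18
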