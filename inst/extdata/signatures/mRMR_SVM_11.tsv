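rank	gene_i	gene_j
1	PCOLCE2	DBH
2	RPLP2	FCN3
3	THY1	DPT
4	GDF15	CHST4
5	PTPRA	DBH
6	RPLP2	ADAMTSL2
7	PPIC	C7
8	EIF2AK1	F8
9	KDSR	FCN2
10	PRDX4	C7
11	KDSR	ASAH1
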