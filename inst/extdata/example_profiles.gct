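#1.3
6	4	1	5
id	gene_symbol	P01	P02	P03	P04
pert_iname	na	drugA	drugA	drugB	drugB
cell_id	na	MCF7	MCF7	HEPG2	HEPG2
pert_dose	na	10	1	10	10
pert_time	na	24	6	24	24
is_gold	na	1	1	1	0
g0001	GENE1	1.25	0.10	-0.44	0.91
g0002	GENE2	-0.75	0.32	1.80	-0.22
g0003	GENE3	0.05	-1.40	0.66	1.05
g0004	GENE4	2.10	0.88	-0.90	0.40
g0005	GENE5	-1.60	-0.25	0.12	-1.10
g0006	GENE6	0.44	1.02	-1.30	0.77
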