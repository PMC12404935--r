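gene_symbol	log2fc	ave_expr	t	p_value	fdr	b
SPINK1	1.2275	7.9677	4.0546	0.0001	0.0193	0.8893
ANPEP	1.1296	8.4200	3.2907	0.0017	0.0398	-1.2752
MT1G	1.0515	10.1510	3.4681	0.0010	0.0326	-0.7976
NR4A1	1.0155	7.2615	4.0990	0.0001	0.0182	1.0232
PRSS2	1.0006	8.0206	3.2764	0.0017	0.0407	-1.3127
SCD5	-1.2022	8.0146	-3.2899	0.0017	0.0398	-1.2771
QPCT	-1.3188	7.2413	-3.8272	0.0003	0.0221	0.2170
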