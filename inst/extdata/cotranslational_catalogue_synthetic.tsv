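study	protein_id	intermediate_index	conformation_label	pdb_id	deposited_start	deposited_end	modeled_start	modeled_end	is_native	excluded	exclusion_reason
Agirrezabala2022	NC1	1	a	70T5	1	27	4	27	FALSE	FALSE	
Agirrezabala2022	NC1	1	b	70II	1	27	12	27	FALSE	TRUE	major modeled-vs-deposited sequence discrepancy
Agirrezabala2022	NC1	1	c	9AX1	1	27	1	27	FALSE	FALSE	
Agirrezabala2022	NC1	2	a	9AX2	1	70	1	70	FALSE	FALSE	
Agirrezabala2022	NC1	2	b	9AX3	1	70	1	70	FALSE	FALSE	
Agirrezabala2022	NC1	2	c	9AX4	1	70	1	70	TRUE	FALSE	
Hanazono2018	NC2	1	a	5B3X	1	20	1	19	FALSE	FALSE	
Hanazono2018	NC2	2	a	5B3Y	1	45	25	45	FALSE	TRUE	major modeled-vs-deposited sequence discrepancy
Hanazono2018	NC2	3	a	5ZCA	1	92	3	92	TRUE	FALSE	
Hanazono2016	NC3	1	a	3W0A	1	17	2	17	FALSE	FALSE	
Hanazono2016	NC3	2	a	9AX5	1	36	1	36	FALSE	FALSE	
Hanazono2016	NC3	3	a	9AX6	1	52	1	52	FALSE	FALSE	
Hanazono2016	NC3	4	a	1MJC	1	69	1	69	TRUE	FALSE	
Cabrita2016	FLN5	1	a	6G4A	1	114	1	114	TRUE	FALSE	
Cabrita2016	FLN5	2	a	2N62	1	221	1	221	FALSE	FALSE	
Cabrita2016	FLN5	2	b	2N62	1	221	1	221	FALSE	FALSE	
Cabrita2016	FLN5	2	c	2N62	1	221	1	221	FALSE	FALSE	
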