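gene	p_value_os	padj_os	genomic_coordinates	disrupted_pir_anchor	n_donors
TFAP2A-AS1	0.00032	0.01472	chr6:10409340-10416446	chr6:99589388-99626140	3
DLX2	0.00288	0.04127	chr2:172099439-172102900	chr2:63042965-63063823	2
DAD1	0.00016	0.00638	chr14:22564905-22589269	chr14:22370281-22410008	2
ZNF142	0.00521	0.04164	chr2:218637916-218659655	chr2:128075688-128101753	2
ELP4	0.00354	0.04127	chr11:31509700-31790328	multiple	3
PRMT5	0.00413	0.04127	chr14:22920511-22929585	chr14:22370281-22410008	2
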