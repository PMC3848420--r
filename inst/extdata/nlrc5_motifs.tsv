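name	mode	body	tolerance	region_start	region_end
walker_A	literal	GKAGMGKT	NA	NA	NA
walker_B	literal	LLIFDGLDEAL	NA	NA	NA
sensor_1	literal	TSR	NA	198	369
AxP	literal	AVP	NA	370	453
WH_consensus	literal	FYAKDI	NA	NA	NA
cys_capping	spacing	23,5,6,12	0	NA	NA
walker_A_general	class	[AG]xxxxGK[ST]	NA	NA	NA
walker_B_general	class	[LIVMF][LIVMF][LIVMF][LIVMF][D]xx[D][E]	NA	NA	NA
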