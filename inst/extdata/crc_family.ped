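# Extended PED: family, member, father, mother, sex, affection, phenotype keyword, age
FAM1	I-2	0	0	2	2	crc_case	60
FAM1	II-1	0	I-2	1	2	crc_case	41
FAM1	II-2	0	I-2	2	2	polyp	45
FAM1	II-4	0	I-2	1	2	crc_case	44
FAM1	II-6	0	I-2	2	2	polyp	46
FAM1	III-2	II-4	0	1	1	unaffected	23
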