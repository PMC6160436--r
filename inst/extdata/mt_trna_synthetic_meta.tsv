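name	strand	genome_start	numbering
MT-TA	L	5587	9:9;34:34
MT-TC	L	5761	9:9;34:34
MT-TD	H	7518	9:9;34:34
MT-TE	L	14674	9:9;34:34
MT-TF	H	577	9:9;34:34
MT-TG	H	9991	9:9;34:34
MT-TH	H	12138	9:9;34:34
MT-TI	H	4263	9:9;34:34
MT-TK	H	8295	9:9;34:34;58:54
MT-TL1	H	3230	9:9;34:34
MT-TL2	H	12266	9:9;34:34
MT-TM	H	4402	9:9;34:34
MT-TN	L	5657	9:9;34:34
MT-TP	L	15956	9:9;34:34
MT-TQ	L	4329	9:9;34:34
MT-TR	H	10405	9:9;16:16;34:34
MT-TS1	H	7446	9:9;34:34
MT-TS2	L	12207	9:9;34:34
MT-TT	H	15888	9:9;34:34
MT-TV	H	1602	9:9;34:34
MT-TW	H	5512	9:9;34:34
MT-TY	L	5826	9:9;34:34
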