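phage	accession	human_gut	urban_ww	poultry_spain	poultry_china	reported_specificity
crAssBcn3	OQ221538	74.0	69.0	26.2	67.8	Quite
crAss001	NC_049977.1	67.3	67.1	26.4	64.7	Quite
crAss002	MN917146.1	90.3	9.8	88.2	7.0	Quite
DAC15	MT074136.1	70.1	6.0	2.8	2.3	High
DAC17	MT074138.1	71.4	6.1	2.4	2.3	High
cr112	MT774388.1	49.1	51.2	23.4	48.1	Quite
cr53	MT774396.1	66.7	27.8	79.2	12.3	Quite
cr50	MT774375.1	47.6	19.9	82.0	16.6	Quite
cr85	MT774390.1	98.1	38.9	24.1	4.6	High
cr6	MT774401.1	90.9	24.4	96.2	13.7	Quite
cr12	MZ130492.1	91.9	25.6	98.0	16.8	Quite
cr107	MT774377.1	90.2	9.0	78.1	7.9	Quite
cr17	MZ130488.1	93.5	7.0	11.6	0.9	High
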