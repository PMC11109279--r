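variant	partner	model	Kd_uM	dH	minus_TdS	dG
WT	DE	one_site	91.6	48.9	-54.3	-5.4
WT	DtcEtc	one_site	38.9	-35.5	29.4	-6.1
WT	D	one_site	122.8	NA	NA	NA
WT	E	one_site	35.3	35.5	-41.6	-6.1
W225A	DE	one_site	16.9	11.8	-18.3	-6.5
R229Q	DE	one_site	5.1	8.6	-15.8	-7.2
R233Q-1	DE	sequential	42.9	5.9	-11.9	-6.0
R233Q-2	DE	sequential	25.3	38.7	-45.1	-6.4
R235Q	DE	one_site	26.0	2.4	-8.7	-6.3
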