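omr	ocher	light	Vmax	Km_mM	kcat	kcat_over_Km
DE	none	dark	17.6	19.2	0.293	20.6
DEm	none	dark	5.1	27.6	0.086	3.7
DE	WT	dark	18.3	10.4	0.304	37.7
DE	WT	light	20.7	6.3	0.344	58.4
DE	R102Q	dark	18.2	14.4	0.303	21.4
DE	R102Q	light	19.5	18.1	0.325	18.1
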