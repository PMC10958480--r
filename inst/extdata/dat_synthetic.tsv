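region	value
left_dorsal_caudate	80
left_dorsal_putamen	100
left_ventral_striatum	70
left_amygdala	10
left_hippocampus	8
left_parahippocampus	6
left_insula	12
left_olfactory	15
left_anterior_cingulate	5
left_middle_cingulate	5
left_postcentral	3
left_precentral	3
right_dorsal_caudate	77.6
right_dorsal_putamen	97
right_ventral_striatum	67.9
right_amygdala	9.7
right_hippocampus	7.76
right_parahippocampus	5.82
right_insula	11.64
right_olfactory	14.55
right_anterior_cingulate	4.85
right_middle_cingulate	4.85
right_postcentral	2.91
right_precentral	2.91
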