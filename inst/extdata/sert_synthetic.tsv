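region	value
left_dorsal_caudate	30
left_dorsal_putamen	25
left_ventral_striatum	40
left_amygdala	75
left_hippocampus	80
left_parahippocampus	60
left_insula	70
left_olfactory	45
left_anterior_cingulate	55
left_middle_cingulate	50
left_postcentral	10
left_precentral	10
right_dorsal_caudate	29.1
right_dorsal_putamen	24.25
right_ventral_striatum	38.8
right_amygdala	72.75
right_hippocampus	77.6
right_parahippocampus	58.2
right_insula	67.9
right_olfactory	43.65
right_anterior_cingulate	53.35
right_middle_cingulate	48.5
right_postcentral	9.7
right_precentral	9.7
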