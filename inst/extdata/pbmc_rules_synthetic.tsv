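cell_type	parent	marker	relation	valley
B	NA	CD19	above_valley	1
T	NA	CD3	above_valley	1
T	NA	CD19	below_valley	1
CD4T	T	CD4	above_valley	2
CD8T	T	CD4	below_valley	1
Mono	NA	CD3	below_valley	1
Mono	NA	CD19	below_valley	1
Mono	NA	CD4	between_valleys	1
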