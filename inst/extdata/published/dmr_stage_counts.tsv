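stage	n_hypo	n_hyper
hyperplasia	1447	471
adenoma_min	1410	594
early_carcinoma	2054	1004
late_carcinoma	2221	1156
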