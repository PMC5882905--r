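stage	n_hypo	n_hyper
hyperplasia	70323	30187
adenoma_min	79147	34900
early_carcinoma	97436	48665
late_carcinoma	100148	49570
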