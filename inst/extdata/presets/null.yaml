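# Null scenario: both conditions identically parameterized, no modulation,
# no condition-specific turnover or phosphosite gain.
protein_label_prob: 0.29
fraction_modulated: 0.0
endogenous_cleavage_prob: 0.05
phospho_detect_prob:
  Control: 0.1
  LPS: 0.1
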