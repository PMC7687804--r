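# Per-layer newly-synthesized pool probabilities matching the reported
# labeled-proteome fractions (Control GC/EC/SMC, LPS GC/EC/SMC).
protein_label_prob:
  "Control:GC": 0.31
  "Control:EC": 0.29
  "Control:SMC": 0.34
  "LPS:GC": 0.16
  "LPS:EC": 0.18
  "LPS:SMC": 0.16
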