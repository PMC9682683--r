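msl: 256
bs: 32
lr: 5.0e-05
epochs: 50
layers: 4
heads: 12
units: 64
encoder_d: 768
feature_set: cont+synt
synt_blocks: both
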