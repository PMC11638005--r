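mode: simulate
seed: 42
n_complexes: 40
n_frames: 300
bleach_prob: 0.01
multiple_weights:
- 0.7
- 0.3
n_boot: 50
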