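{"brightness_pe":57.5261094093526,"uncertainty_pe":11.6173105369974,"n_tracks":40,"peaks":[4.9,9.695],"periodicity_mode":4.83358679367779,"ci95":[4.83358679367779,4.83358679367779],"n_intervals":1}
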