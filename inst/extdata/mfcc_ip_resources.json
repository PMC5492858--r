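{
  "schema": "wasnbird-ip-resources/1",
  "comment": "Feature-extraction IP: per-component figures come from components implemented separately for inspection, so they do not sum to the packaged-IP total; the total row is what fit computations use.",
  "components": {
    "fifos_2x_depth_2048": {"cycles": null,  "dsp": 0,  "bram_blocks": 4,  "lut": 218,  "ff": 0},
    "fft_fsm":             {"cycles": 28713, "dsp": 23, "bram_blocks": 7,  "lut": 1551, "ff": 1933},
    "ram":                 {"cycles": null,  "dsp": 0,  "bram_blocks": 1,  "lut": 0,    "ff": 0},
    "rom":                 {"cycles": null,  "dsp": 0,  "bram_blocks": 64, "lut": 32,   "ff": 1},
    "mfcc_fsm":            {"cycles": 49156, "dsp": 2,  "bram_blocks": 0,  "lut": 773,  "ff": 1263},
    "log":                 {"cycles": null,  "dsp": 4,  "bram_blocks": 0,  "lut": 710,  "ff": 1192},
    "dct_fsm":             {"cycles": 53,    "dsp": 2,  "bram_blocks": 1,  "lut": 1254, "ff": 2987}
  },
  "total": {"dsp": 31, "bram_blocks": 73, "lut": 4489, "ff": 7677},
  "critical_path_cycles": 49156
}
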