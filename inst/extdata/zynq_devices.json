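{
  "schema": "wasnbird-device-catalog/1",
  "comment": "Zynq-7000 family capacities: look-up tables, flip-flops, 36 Kb block-RAM blocks, DSP slices.",
  "devices": {
    "XC7Z010": {"lut": 17600,  "ff": 35200,  "bram_blocks": 60,  "dsp": 80},
    "XC7Z015": {"lut": 46200,  "ff": 92400,  "bram_blocks": 95,  "dsp": 160},
    "XC7Z020": {"lut": 53200,  "ff": 106400, "bram_blocks": 140, "dsp": 220},
    "XC7Z030": {"lut": 78600,  "ff": 157200, "bram_blocks": 265, "dsp": 400},
    "XC7Z035": {"lut": 171900, "ff": 343800, "bram_blocks": 500, "dsp": 900},
    "XC7Z045": {"lut": 218600, "ff": 437200, "bram_blocks": 545, "dsp": 900},
    "XC7Z100": {"lut": 277400, "ff": 554800, "bram_blocks": 755, "dsp": 2020}
  }
}
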