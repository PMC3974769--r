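{
  "comment": "Synthetic 7TM amplicon topology (TM2-TM7, 215 aa) for testing; binding positions are 0-based amino-acid alignment columns. 23 of the 26 positions lie in TM3-TM6, 2 in TM2 and 1 in TM7, mirroring the layout of published odorant-binding-site models.",
  "binding_positions": [4, 11, 40, 43, 44, 47, 48, 51, 80, 83, 84, 87, 88, 130, 133, 134, 137, 138, 141, 176, 179, 180, 183, 184, 187, 200]
}
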