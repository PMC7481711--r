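# Two patients with mismatched compliance on the modified splitter.
# All values in clinical units (cmH2O, L, s).
ventilator:
  pip: 20.33
  peep: 5
  rr: 15
  ie: [1, 2]
splitter:
  topology: modified
  r_i: 0.06
  r_e: 0.06
  r_v1: 18
  r_v2: 0
patients:
  - A          # healthy reference lung
  - D          # severe ARDS: 40% compliance reduction
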