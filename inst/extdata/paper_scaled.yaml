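# Desk-scale tournament: same structure as the full study but with
# tau = 256 and 50 Monte-Carlo repetitions per pair.
phenotypes: [tom0, tom1, tom2, tom3, tom4]
tournament:
  tau: 256
  n_reps: 50
  seed: 1
egt:
  n_init: 64
output: runs/scaled
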