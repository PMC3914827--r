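# Full-scale study conditions: tau = 512 trials per iterated game,
# 500 Monte-Carlo repetitions per phenotype pair, 128 replicator initial
# conditions for the evolutionary analysis.
phenotypes: [tom0, tom1, tom2, tom3, tom4]
tournament:
  tau: 512
  n_reps: 500
  seed: 1
egt:
  n_init: 128
output: runs/full
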