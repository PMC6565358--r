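# Small end-to-end demo: 6 synthetic participants, 2 + 2 blocks,
# reduced permutation count. Completes on one CPU in about a minute.
nParticipants: 6
seed: 42
task:
  nBlocksLow: 2
  nBlocksHigh: 2
erp:
  nPerCondition: 10
cluster:
  nPermutations: 200
  window: [300, 600]
microstates:
  kRange: [2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
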