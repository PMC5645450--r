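query_gene: g0001
seed: 20240401
regulators:
- compound_id: c0015
  direction: up
  effect: 3.0
- compound_id: c0004
  direction: up
  effect: 3.0
- compound_id: c0012
  direction: up
  effect: 3.0
- compound_id: c0010
  direction: up
  effect: 3.0
- compound_id: c0008
  direction: down
  effect: -3.0
- compound_id: c0007
  direction: down
  effect: -3.0
- compound_id: c0003
  direction: down
  effect: -3.0
- compound_id: c0002
  direction: down
  effect: -3.0
signal_targets:
- target_id: T_SIGNAL_UP_01
  direction: up
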