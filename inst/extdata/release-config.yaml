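# Example release-scenario configuration: stem beetle on a 100-node stand,
# with the Holling constant overridden to 1.
model: coupled
species: stem
parameters:
  alpha: 1
scenario:
  P0: 100
  B0: 20
  horizon: 1000
  eps: 1
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
  g_form: leaf_per_node
seed: 1
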