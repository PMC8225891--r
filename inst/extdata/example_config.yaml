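# Example run configuration for the packaged synthetic duplex
# (example_duplex.edges: 30 nodes, 80 edges per layer, 60% edge overlap).
target: target
auxiliary: aux
measure: ra
methods:
  - simbins
  - target
  - sum
b_target: 5
b_aux: 5
train_ratio: 0.9
negative_ratio: 2
auc_n: 2000
iterations: 2
seed: 1
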