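# Default random-search space for the localization network.
# Values are candidate lists sampled uniformly by random_search().
hidden:
  - [128, 128, 64]
  - [256, 128, 64]
  - [64, 64, 32]
input_dropout: [0.0, 0.1, 0.2]
hidden_dropout: [0.3, 0.5]
l1: [0.0, 1.0e-4, 1.0e-3, 3.0e-3]
l2: [0.0, 1.0e-4, 1.0e-3]
learning_rate: [0.001, 0.005, 0.01]
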