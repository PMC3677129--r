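# Desk-scale variant of the strong-scaling protocol: small enough to run
# on one CPU in seconds while exercising the full factorial.
scaling: strong
node_counts: [2, 4, 8]
neurons: 512
connections_per_neuron: 16
rates: [10, 30, 50, 80]
duration: 0.1
dt: 0.001
trials: 2
pivot_set: [0, 1, 2, 32]
seed: 1
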