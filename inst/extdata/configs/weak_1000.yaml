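# Weak scaling, 1000 connections per neuron: 250,000 neurons per node
scaling: weak
node_counts: [8, 16, 32, 64, 96]
neurons: 250000
connections_per_neuron: 1000
rates: [10, 30, 50, 80]
duration: 1
dt: 0.001
trials: 3
pivot_set: [0, 1, 2, 3, 10, 20, 32]
seed: 1
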