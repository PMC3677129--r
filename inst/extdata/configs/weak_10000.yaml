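# Weak scaling, 10,000 connections per neuron: 31,250 neurons per node
scaling: weak
node_counts: [8, 16, 32, 64, 96]
neurons: 31250
connections_per_neuron: 10000
rates: [10, 30, 50, 80]
duration: 1
dt: 0.001
trials: 3
pivot_set: [0, 1, 2, 3, 10, 20, 32]
seed: 1
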