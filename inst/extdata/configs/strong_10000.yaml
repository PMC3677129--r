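# Strong scaling, 10,000 connections per neuron (cluster scale; needs force)
scaling: strong
node_counts: [8, 16, 32, 64, 96]
neurons: 250000
connections_per_neuron: 10000
rates: [10, 30, 50, 80]
duration: 1
dt: 0.001
trials: 3
pivot_set: [0, 1, 2, 3, 10, 20, 32]
seed: 1
# NOTE: 250,000 is not a multiple of 64 or 96; round the neuron count to a
# nearby multiple (e.g. 249,600) before running those rows.
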