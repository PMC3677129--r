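# Strong scaling, 1000 connections per neuron (cluster scale; needs force)
scaling: strong
node_counts: [8, 16, 32, 64, 96]
neurons: 2000000
connections_per_neuron: 1000
rates: [10, 30, 50, 80]
duration: 1
dt: 0.001
trials: 3
pivot_set: [0, 1, 2, 3, 10, 20, 32]
seed: 1
# NOTE: 2,000,000 is not a multiple of 96, so the 96-node row cannot be
# split into exactly equal blocks; round the neuron count to a nearby
# multiple (e.g. 1,999,872) before running that row.
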