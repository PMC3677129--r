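# Shared fixtures, built in code at test time.

# Four-node partition mirroring the hybrid-scheme illustration: node 0 has
# 2000 neurons projecting to node 1, 1000 to node 2 and 5000 to node 3.
# Ownership is balanced at 8000 neurons per node.
figure2_partition <- function() {
  owner <- rep(0:3, each = 8000L)
  network_partition(owner, 4L, list(
    projection_map(0L, 1L, 0:1999),
    projection_map(0L, 2L, 2000:2999),
    projection_map(0L, 3L, 3000:7999)))
}

# Two nodes, one projection of exactly N members from node 0 to node 1.
two_node_projection <- function(N) {
  owner <- rep(0:1, each = N)
  network_partition(owner, 2L, list(
    projection_map(0L, 1L, 0:(N - 1L))))
}

# Brute-force reference for remote spike delivery: the set of fired neurons
# owned elsewhere that have at least one synapse onto a node-owned target.
brute_force_remote_spikes <- function(net, part, fired, dst) {
  pre <- net$connections[, "pre"]
  post <- net$connections[, "post"]
  hit <- part$owner[post + 1L] == dst &
    part$owner[pre + 1L] != dst &
    pre %in% fired
  sort(unique(pre[hit]))
}

# Step-spike helper drawing a random firing set of size S over N indices.
random_step <- function(N, S) {
  step_spikes(sample.int(N, S) - 1L, N)
}
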