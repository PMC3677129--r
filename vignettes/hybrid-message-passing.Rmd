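---
title: "Hybrid spike message passing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid spike message passing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridspike)
```

## The problem

A distributed spiking-network simulation alternates between integrating
the neuron equations on each compute node and exchanging the resulting
spikes. The exchange volume is what this package models. Two encodings are
in common use. Address-event representation (AER) sends the identifier of
every neuron that fired, so message size tracks activity. Bit-packing
sends one bit per output neuron, so message size is fixed by the
projection size alone — rate-independent, but wasteful at the low rates
typical of cortex-like activity.

The hybrid scheme keeps both and decides per projection and per time step.
With `N` source neurons projecting onto a given remote node and `S` of
them firing this step, the codec uses AER while `S <= F` and bit-packing
once `S > F`, where

```
F = P * N / 32
```

with 32 the payload word width in bits and `P` the *pivot multiplier*. At
`P = 1` the switch sits exactly at the packet-size crossover, so the
chosen packet is never larger than the better pure scheme and every
message is bounded by `ceiling(N/32)` payload words — a deterministic
upper bound no matter how synchronously the population fires. `P = 0` and
`P = 32` recover pure bit-packing and pure AER as degenerate settings.

```{r}
threshold(2000, 1)   # F for a 2000-neuron projection at P = 1
gpe_worked_example() # the 576-neuron packet-size curves
```

## Assumptions

* **Words, not wall-clock.** Communication cost is accounted in 32-bit
  words (one header word plus payload) and bytes. Wall-clock exchange time
  depends on the interconnect (fabric, topology, MPI implementation) and
  is deliberately out of scope; word count is the deterministic,
  hardware-independent proxy, and per-packet payload counts exclude the
  header so that the 2000-neuron/72-firing example reads 63 versus 72.
* **One packet per connected pair per step.** A node sends along each
  outgoing projection exactly once per iteration, including an empty
  header-only packet when nothing fired, so receivers advance
  deterministically. Unconnected node pairs exchange nothing.
* **Dummy-neuron fan-out.** A remote neuron's spike crosses a node
  boundary at most once; the local mirror (dummy neuron) relays it to all
  local targets. Projection membership therefore de-duplicates multiple
  synapses onto the same destination node.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `P` (pivot multiplier) | dimensionless, 0–32 | 1 | exact packet-size crossover; benchmark sweeps use {0, 1, 2, 3, 10, 20, 32} |
| `dt` | s | 0.001 | 1 ms integration step, the grid the codecs operate on |
| `rate` | Hz | 10/30/50/80 in the reference grids | spans low cortical to high pathological activity |
| `duration` | s | 1 (reference), shorter in tests | one second of activity per trial |
| `trials` | count | 3 | lowest-cost trial reported, damping generator luck |
| `window_sigma` | s | 0.010 | Gaussian rate-curve window; the kernel is named by the validation protocol but its width is not, and 10 ms resolves rate transients at 1 ms steps without drowning in step noise |

## The synthetic workload

`generate_network()` draws, per neuron, a fixed number of outgoing
connections uniformly without replacement over all other neurons — no
self-connections, no duplicate targets. Uniform random connectivity is the
stated benchmark topology; exclusion of autapses and multapses is this
package's choice, since neither adds communication-relevant structure
(a duplicate synapse changes no projection membership).
`partition_network()` shuffles neuron ids with a seeded stream and assigns
contiguous equal blocks, the simplest reproducible reading of a random
equal split. Because blocks are contiguous over one permutation per root
seed, partitions at nested node counts refine each other, which is what
makes the cost-versus-nodes comparison monotone in the tests.

`generate_spikes()` realises "Poisson activity centred at the target
frequency" as a homogeneous per-neuron Bernoulli process with per-step
probability `rate * dt` (rejected when `rate * dt >= 1`). The alternative
reading — per-neuron rates drawn from a distribution centred on the
target — would spread the per-neuron rate histogram further; the
homogeneous choice is the simpler model and its binomial spread is already
qualitatively consistent with the validation statistics (rate histogram,
ISI coefficient of variation near 1).

What this workload does *not* emulate: refractoriness, bursting,
correlated or oscillatory population activity, heterogeneous degree
distributions, and spatially structured connectivity. Passing tests
therefore demonstrate codec and protocol correctness and cost behaviour
under uniform random conditions, not cost figures for any particular
biological model; structured activity concentrates spikes in time and
would shift the observed benefit of the hybrid scheme in either direction.

## Numerical and representational choices

* **Header width.** The wire convention dispatches on the header's sign: a
  non-negative value is an AER firing count, negative marks bit-packing.
  A literal one-byte header cannot hold counts for projections beyond 127
  members, so the header here is one signed 32-bit word. Wire
  compatibility with byte-header implementations is not claimed.
* **Tie-break.** `S == F` uses AER (`S <= F` is the rule, kept in exact
  arithmetic: `F` stays rational, e.g. 62.5 for `N = 2000, P = 1`, and is
  never pre-rounded).
* **`P = 0` with `S = 0`.** The empty AER packet (header only) is sent,
  since `S <= F = 0` holds; it is never larger than a bitmask and keeps
  the rule literal. Strictly, pure bit-packing "always" would ship the
  full bitmask even for silence.
* **Bit order.** LSB-first within a word, words in ascending local-index
  order; local indices are positions in the ascending-by-global-id member
  list. The wire format is little-endian throughout and documented in
  `?write_packets` so independent implementations can interoperate.
* **Seed streams.** One root seed; connectivity, partition and spike
  generation derive child seeds by fixed offsets (`?derive_seed`), so each
  module is independently reproducible.
* **Degenerate inputs.** Zero-rate rasters, empty firing sets, single-node
  partitions and silent steps are all legal and exercised; malformed
  packets (payload length inconsistent with the header, indices or set
  bits beyond `N`) raise distinct errors at decode.

## The exchange layer and its modes

Three mechanisms are exposed — blocking point-to-point, non-blocking
point-to-point, and the variable-size collective (`alltoallv`) — behind a
single contract: per iteration, one packet per existing projection pair,
every destination receives exactly what was addressed to it, and decoded
content is independent of delivery order. On the bundled loopback backend
the three modes are semantically identical and produce identical cost
records; they differ only in scheduling on a real transport, which is
hardware territory this package does not model. A real MPI mapping is one
process per simulated node with point-to-point sends/receives (receives
posted before sends in the non-blocking mode) or a single variable
all-to-all call per step, with per-destination counts taken from the
packet lengths; no MPI bindings are bundled, and `transport(backend =
"mpi")` says so rather than pretending.

## The benchmark harness

`run_experiment()` runs the full factorial of rates × pivots for each node
count, replaying the *same* raster under every codec within a (rate,
trial) cell so cost differences are attributable to the codec alone, and
reports the lowest-cost trial per cell. η is the mean over rates of the
percent cost reduction against the matched AER baseline, reported at every
pivot and summarised at the empirically best pivot per node count; at
`P = 32` the hybrid path is byte-identical to AER and η is exactly 0,
which the tests assert at the packet-stream level.

Problem sizes: the reference grids (8–96 nodes, 2,000,000 neurons at 1000
connections or 250,000 at 10,000, 1 s, 3 trials) ship as YAML under
`inst/extdata/configs/` but are cluster-sized; `experiment_config()`
refuses anything above 10^7 neuron-steps per trial unless `force = TRUE`.
The test suite and the shipped `desk_scale.yaml` run scaled-down grids
(hundreds of neurons, tens of milliseconds, 2–8 nodes), which exercise
every code path while keeping the default check fast. Two reference rows
(2,000,000 neurons on 96 nodes; 250,000 on 64 or 96) are not divisible by
their node counts and are rejected by the equal-split rule as shipped; the
config files carry a rounding note.

## Known limitations

* No wall-clock or contention model: word counts cannot reproduce
  transport-level effects (the relative ranking of blocking versus
  non-blocking versus collective exchange on real fabrics, or their
  anomalies).
* The time-fraction statistics of any particular biological model (how
  often a given population sits above its crossing point) depend on that
  model's dynamics and are not computed here; only the deterministic
  packet-size curves and crossing point are.
* Pivot selection is static per run; adapting `P` online as activity
  drifts is an obvious extension the data structures permit but the
  harness does not implement.
* The desk-scale η figures quantify the word-count model at small scale;
  fractions of cells improved on specific hardware are not claimed.
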