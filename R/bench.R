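# Scaling benchmark harness. Drives the full factorial of target firing
# rates x pivot points over strong- or weak-scaling node counts, accounts
# per-run communication cost in 32-bit words, applies the best-of-trials
# rule, and computes the average percent improvement (eta) of the hybrid
# scheme over a matched AER baseline run on identical spike trains.

#' Build a scaling experiment configuration
#'
#' Strong scaling holds the total network size fixed while the node count
#' grows; weak scaling holds the per-node neuron count fixed so the network
#' grows with the nodes. The reference experiment grids (node counts 8, 16,
#' 32, 64, 96; 2,000,000 neurons at 1000 connections each or 250,000 at
#' 10,000; rates 10, 30, 50, 80 Hz; pivots {0, 1, 2, 3, 10, 20, 32}; 1 s
#' runs, 3 trials) ship as YAML files under `inst/extdata/configs/` but are
#' cluster-sized; a guard refuses configurations above `10^7` neuron-steps
#' per trial unless `force = TRUE`.
#'
#' @param scaling `"strong"` or `"weak"`.
#' @param node_counts simulated compute node counts.
#' @param neurons total neurons (strong) or neurons per node (weak); every
#'   implied total must be divisible by its node count.
#' @param connections_per_neuron outgoing connections per neuron.
#' @param rates target Poisson rates in Hz.
#' @param duration run length in seconds.
#' @param dt integration step in seconds.
#' @param trials number of trials; the lowest-cost trial is reported.
#' @param pivot_set hybrid pivot multipliers to sweep.
#' @param seed root seed.
#' @param force bypass the desk-scale guard.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(scaling = c("strong", "weak"),
                              node_counts = c(2, 4, 8),
                              neurons = 512,
                              connections_per_neuron = 16,
                              rates = c(10, 30, 50, 80),
                              duration = 1, dt = 0.001, trials = 3,
                              pivot_set = c(0, 1, 2, 3, 10, 20, 32),
                              seed = 1, force = FALSE) {
  scaling <- match.arg(scaling)
  stopifnot(all(node_counts >= 1), neurons >= 2,
            connections_per_neuron >= 1, all(rates >= 0), duration > 0,
            dt > 0, trials >= 1, all(pivot_set >= 0 & pivot_set <= 32))
  totals <- if (scaling == "strong") rep(neurons, length(node_counts))
            else neurons * node_counts
  if (any(totals %% node_counts != 0)) {
    stop("every node count must divide its total neuron count", call. = FALSE)
  }
  if (any(connections_per_neuron > totals - 1)) {
    stop("connections_per_neuron must be <= total neurons - 1", call. = FALSE)
  }
  n_steps <- round(duration / dt)
  neuron_steps <- max(totals) * n_steps
  if (neuron_steps > 1e7 && !force) {
    stop("configuration needs ", format(neuron_steps, big.mark = ","),
         " neuron-steps per trial (limit 1e7); this is a cluster-scale run.",
         " Pass force = TRUE to proceed anyway", call. = FALSE)
  }
  structure(
    list(scaling = scaling, node_counts = as.integer(node_counts),
         neurons = as.integer(neurons),
         connections_per_neuron = as.integer(connections_per_neuron),
         rates = as.numeric(rates), duration = duration, dt = dt,
         trials = as.integer(trials), pivot_set = as.numeric(pivot_set),
         seed = as.integer(seed)),
    class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [experiment_config()].
#' @param force bypass the desk-scale guard.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path, force = FALSE) {
  y <- yaml::read_yaml(path)
  do.call(experiment_config, c(y, list(force = force)))
}

.total_neurons <- function(cfg, nodes) {
  if (cfg$scaling == "strong") cfg$neurons else cfg$neurons * nodes
}

#' Run a scaling experiment
#'
#' For each node count a network is generated and partitioned once; for
#' each (rate, trial) cell one Poisson raster is generated and replayed
#' unchanged under every codec mode — the pure AER baseline plus the hybrid
#' codec at each pivot in `pivot_set` — so cost differences are attributable
#' to the codec alone. The reported cost per cell is the minimum over
#' trials of the run's total word count (headers included). eta is the mean
#' over rates of the percent cost reduction relative to the AER baseline,
#' reported at every pivot and summarised at the empirically best pivot per
#' node count.
#'
#' @param cfg an [experiment_config()].
#' @param transport a [transport()] (loopback modes are cost-equivalent).
#' @return an object of class `bench_result`: `raw` (per nodes, rate,
#'   codec, trial total words), `best` (best-of-trials costs), `eta` (per
#'   nodes and pivot), `eta_best` (best pivot per node count), `config`.
#' @export
run_experiment <- function(cfg, transport = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(transport)) transport <- hybridspike::transport("nonblocking")
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  codecs <- c("aer", paste0("P", cfg$pivot_set))
  raw <- list()
  for (nodes in cfg$node_counts) {
    total <- .total_neurons(cfg, nodes)
    net <- generate_network(total, cfg$connections_per_neuron, cfg$seed)
    part <- partition_network(net, nodes, cfg$seed)
    for (ri in seq_along(cfg$rates)) {
      rate <- cfg$rates[ri]
      for (trial in seq_len(cfg$trials)) {
        raster <- generate_spikes(rate, total, cfg$duration, cfg$dt,
                                  seed = cfg$seed + 1000L * trial + ri)
        for (cd in codecs) {
          mode <- if (cd == "aer") "aer" else "hybrid"
          pivot <- if (cd == "aer") NA_real_
                   else as.numeric(sub("^P", "", cd))
          total_words <- 0
          for (t in seq_len(n_steps)) {
            cr <- run_iteration(part, raster$spikes[[t]], codec_mode = mode,
                                pivot = if (is.na(pivot)) 1 else pivot,
                                transport = transport, iteration = t - 1L)
            total_words <- total_words + cr$total_words
          }
          raw[[length(raw) + 1L]] <- data.frame(
            nodes = nodes, rate = rate, codec = cd, pivot = pivot,
            trial = trial, total_words = total_words)
        }
      }
    }
  }
  raw <- do.call(rbind, raw)

  # best-of-trials: lowest total cost per (nodes, rate, codec) cell
  best <- stats::aggregate(total_words ~ nodes + rate + codec + pivot,
                           data = transform(raw,
                                            pivot = ifelse(is.na(pivot), -1,
                                                           pivot)),
                           FUN = min)
  best$pivot <- ifelse(best$pivot < 0, NA_real_, best$pivot)

  eta <- list()
  for (nodes in unique(best$nodes)) {
    b <- best[best$nodes == nodes, ]
    aer <- b[b$codec == "aer", ]
    aer <- aer[order(aer$rate), "total_words"]
    for (p in cfg$pivot_set) {
      h <- b[b$codec == paste0("P", p), ]
      h <- h[order(h$rate), "total_words"]
      eta[[length(eta) + 1L]] <- data.frame(
        nodes = nodes, pivot = p,
        eta_pct = percent_improvement(h, aer))
    }
  }
  eta <- do.call(rbind, eta)
  eta_best <- do.call(rbind, lapply(split(eta, eta$nodes), function(d) {
    d[which.max(d$eta_pct), ]
  }))
  rownames(eta_best) <- NULL
  structure(list(raw = raw, best = best, eta = eta, eta_best = eta_best,
                 config = cfg),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat("Scaling benchmark (", x$config$scaling, "scaling ):",
      length(x$config$node_counts), "node counts x",
      length(x$config$rates), "rates x", length(x$config$pivot_set),
      "pivots,", x$config$trials, "trials\n")
  cat("Best pivot per node count (eta = mean % cost reduction vs AER):\n")
  print(x$eta_best, row.names = FALSE)
  invisible(x)
}

#' Average percent improvement over an AER baseline
#'
#' `eta = mean over rates of 100 * (aer - hybrid) / aer`, the average taken
#' across the target activity rates because large-scale networks rarely
#' maintain a uniform firing rate.
#'
#' @param hybrid_costs per-rate hybrid costs.
#' @param aer_costs matched per-rate AER baseline costs (same spikes, same
#'   seed); must be positive.
#' @return eta in percent; `NA` with a warning if any baseline is zero.
#' @export
#' @examples
#' percent_improvement(c(90, 80, 100, 70), c(100, 100, 100, 100))  # 15
percent_improvement <- function(hybrid_costs, aer_costs) {
  stopifnot(length(hybrid_costs) == length(aer_costs),
            length(aer_costs) >= 1)
  if (any(aer_costs <= 0)) {
    warning("zero AER baseline cost: eta undefined")
    return(NA_real_)
  }
  mean(100 * (aer_costs - hybrid_costs) / aer_costs)
}

#' Packet-size worked example for a 576-neuron output population
#'
#' Reproduces the deterministic packet-size curves for a basal-ganglia
#' (GPe) population of 576 output neurons at a 1 ms integration step: AER
#' payload grows linearly with the number of firings S while the bit-packed
#' payload is a constant `ceiling(576/32) = 18` words, so bit-packing wins
#' once more than 18 neurons — 3.125% of the population — fire in a step.
#' All word counts are produced by the actual encoders.
#'
#' @param N output population size (default 576).
#' @return an object of class `gpe_example`: `table` (S, aer_words,
#'   bitpacked_words, hybrid_words for P = 1), `N`, `bitpacked_words`,
#'   `crossing_S` and `crossing_fraction_pct`.
#' @export
gpe_worked_example <- function(N = 576L) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  bp_words <- packet_payload_words(encode_bitpacked(step_spikes(integer(0), N)))
  S <- 0:N
  aer_words <- integer(length(S))
  hybrid_words <- integer(length(S))
  for (i in seq_along(S)) {
    sp <- step_spikes(seq_len(S[i]) - 1L, N)
    aer_words[i] <- packet_payload_words(encode_aer(sp))
    hybrid_words[i] <- packet_payload_words(encode_hybrid(sp, 1))
  }
  structure(
    list(table = data.frame(S = S, aer_words = aer_words,
                            bitpacked_words = bp_words,
                            hybrid_words = hybrid_words),
         N = N, bitpacked_words = bp_words, crossing_S = bp_words,
         crossing_fraction_pct = 100 * bp_words / N),
    class = "gpe_example")
}

#' @export
print.gpe_example <- function(x, ...) {
  cat("Packet-size worked example, N =", x$N, "output neurons\n")
  cat("  bit-packed payload:", x$bitpacked_words, "words regardless of S\n")
  cat("  AER payload: S words; sizes cross at S =", x$crossing_S,
      sprintf("(%.3f%% of the population)\n", x$crossing_fraction_pct))
  cat("  hybrid (P = 1) payload: min of the two at every S\n")
  invisible(x)
}

#' Plot packet-size curves from a worked example
#'
#' @param example a [gpe_worked_example()] result.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_packet_sizes <- function(example) {
  stopifnot(inherits(example, "gpe_example"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tb <- example$table
  df <- data.frame(
    S = rep(tb$S, 3),
    words = c(tb$aer_words, tb$bitpacked_words, tb$hybrid_words),
    scheme = rep(c("AER", "bit-packed", "hybrid (P = 1)"),
                 each = nrow(tb)))
  ggplot2::ggplot(df, ggplot2::aes(x = S, y = words, colour = scheme)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "neurons fired in step (S)",
                  y = "payload words (32-bit)",
                  title = sprintf("Packet size, N = %d output neurons",
                                  example$N)) +
    ggplot2::theme_minimal()
}
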