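# Poisson spike-train generation on a fixed time grid and the raster
# statistics used to validate it (population rate under a Gaussian window,
# per-neuron rates, ISI coefficient of variation).

#' Generate Poisson spiking activity
#'
#' Every neuron fires independently at each time step with probability
#' `rate * dt` (the discrete Bernoulli approximation of a homogeneous
#' Poisson point process centred at the target frequency). Draws come from
#' the `"spikes"` child stream of `seed`, consumed one step at a time in
#' neuron order, so the raster is reproducible and matches a step-by-step
#' Bernoulli implementation on the same stream.
#'
#' @param rate target firing rate in Hz (>= 0; `rate * dt` must be < 1).
#' @param n_neurons number of neurons.
#' @param duration simulated time in seconds.
#' @param dt integration time step in seconds (default 0.001, i.e. 1 ms).
#' @param seed integer root seed.
#' @return an object of class `spike_raster`: `n_neurons`, `dt`, `n_steps`,
#'   and `spikes`, a list with one sorted vector of 0-based neuron ids per
#'   step.
#' @export
#' @examples
#' r <- generate_spikes(50, 200, 1, seed = 1)
#' sum(lengths(r$spikes)) / (200 * 1)  # empirical mean rate, Hz
generate_spikes <- function(rate, n_neurons, duration, dt = 0.001, seed = 1L) {
  stopifnot(rate >= 0, n_neurons >= 1, duration > 0, dt > 0)
  p <- rate * dt
  if (p >= 1) {
    stop("rate * dt = ", p, " >= 1: the per-step Bernoulli approximation ",
         "is invalid at this rate/step combination", call. = FALSE)
  }
  n_neurons <- as.integer(n_neurons)
  n_steps <- as.integer(round(duration / dt))
  spikes <- vector("list", n_steps)
  if (p == 0) {
    for (t in seq_len(n_steps)) spikes[[t]] <- integer(0)
  } else {
    set.seed(derive_seed(seed, "spikes"))
    # column t holds the n_neurons uniform draws of step t
    u <- matrix(stats::runif(n_neurons * n_steps) < p, nrow = n_neurons)
    for (t in seq_len(n_steps)) spikes[[t]] <- which(u[, t]) - 1L
  }
  structure(
    list(n_neurons = n_neurons, dt = dt, n_steps = n_steps, spikes = spikes),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  total <- sum(lengths(x$spikes))
  cat("Spike raster:", x$n_neurons, "neurons,", x$n_steps, "steps of",
      x$dt * 1000, "ms,", total, "spikes (mean",
      round(total / (x$n_neurons * x$n_steps * x$dt), 2), "Hz)\n")
  invisible(x)
}

#' Per-neuron spike times of a raster
#'
#' @param raster a `spike_raster`.
#' @return list of numeric vectors of spike times in seconds (one per
#'   neuron; step `t` is stamped at `(t - 1) * dt`).
#' @export
spike_times <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  len <- lengths(raster$spikes)
  ids <- unlist(raster$spikes, use.names = FALSE)
  t_s <- rep((seq_len(raster$n_steps) - 1L) * raster$dt, len)
  out <- vector("list", raster$n_neurons)
  for (i in seq_len(raster$n_neurons)) out[[i]] <- numeric(0)
  if (length(ids)) {
    by_neuron <- split(t_s, factor(ids, levels = 0:(raster$n_neurons - 1L)))
    out <- unname(lapply(by_neuron, unname))
  }
  out
}

#' Raster validation statistics
#'
#' Computes the population firing-rate time course (per-step spike counts
#' convolved with a normalised Gaussian window, scaled to Hz per neuron),
#' per-neuron rates, and each neuron's inter-spike-interval coefficient of
#' variation (std/mean of its ISIs; ~1 for a Poisson process, 0 for a
#' perfectly regular train). Neurons with fewer than 3 spikes have fewer
#' than 2 ISIs and get `NA` CV, flagged in `cv_defined`.
#'
#' @param raster a `spike_raster`.
#' @param window_sigma Gaussian window width (standard deviation) in
#'   seconds; the kernel is truncated at +/- 4 sigma. Default 0.010 (10 ms).
#' @return an object of class `raster_stats`: `mean_rate` (Hz),
#'   `rate_curve` (Hz per step), `per_neuron_rate`, `per_neuron_cv`,
#'   `cv_defined`, `window_sigma`, `dt`.
#' @export
compute_stats <- function(raster, window_sigma = 0.010) {
  stopifnot(inherits(raster, "spike_raster"), raster$n_steps >= 1,
            window_sigma > 0)
  counts <- lengths(raster$spikes)
  duration <- raster$n_steps * raster$dt
  mean_rate <- sum(counts) / (raster$n_neurons * duration)

  half <- ceiling(4 * window_sigma / raster$dt)
  k <- stats::dnorm((-half:half) * raster$dt, sd = window_sigma)
  k <- k / sum(k)  # unit mass: smoothing conserves total spike count
  padded <- c(numeric(half), counts, numeric(half))
  sm <- stats::filter(padded, k, sides = 2)
  rate_curve <- as.numeric(sm[(half + 1):(half + raster$n_steps)]) /
    (raster$n_neurons * raster$dt)

  times <- spike_times(raster)
  n_sp <- lengths(times)
  per_neuron_rate <- n_sp / duration
  per_neuron_cv <- rep(NA_real_, raster$n_neurons)
  for (i in which(n_sp >= 3L)) {
    isi <- diff(times[[i]])
    m <- mean(isi)
    per_neuron_cv[i] <- if (m > 0) stats::sd(isi) / m else NA_real_
  }
  structure(
    list(mean_rate = mean_rate, rate_curve = rate_curve,
         per_neuron_rate = per_neuron_rate, per_neuron_cv = per_neuron_cv,
         cv_defined = n_sp >= 3L, window_sigma = window_sigma,
         dt = raster$dt),
    class = "raster_stats")
}

#' @export
print.raster_stats <- function(x, ...) {
  cat("Raster statistics: mean rate", round(x$mean_rate, 3), "Hz; median CV",
      round(stats::median(x$per_neuron_cv, na.rm = TRUE), 3),
      "(", sum(!x$cv_defined), "neurons with <3 spikes )\n")
  invisible(x)
}

#' Export a raster as two-column TSV
#'
#' Columns are `time_s` and `neuron_id`; commented header lines record
#' `n_neurons`, `dt` and `n_steps` so the raster round-trips through
#' [read_raster()].
#'
#' @param raster a `spike_raster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  len <- lengths(raster$spikes)
  df <- data.frame(
    time_s = rep((seq_len(raster$n_steps) - 1L) * raster$dt, len),
    neuron_id = unlist(raster$spikes, use.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_neurons=%d", raster$n_neurons),
               sprintf("# dt=%.10g", raster$dt),
               sprintf("# n_steps=%d", raster$n_steps),
               "time_s\tneuron_id"), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path TSV file with the commented metadata header.
#' @return a `spike_raster`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  getv <- function(key) {
    m <- sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="),
                                               meta, value = TRUE))
    as.numeric(m[1])
  }
  n_neurons <- as.integer(getv("n_neurons"))
  dt <- getv("dt")
  n_steps <- as.integer(getv("n_steps"))
  body <- lines[!grepl("^#", lines)][-1]  # drop column header
  spikes <- vector("list", n_steps)
  for (t in seq_len(n_steps)) spikes[[t]] <- integer(0)
  if (length(body) && nzchar(body[1])) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    t_s <- vapply(parts, function(p) as.numeric(p[1]), 0)
    id <- vapply(parts, function(p) as.integer(p[2]), 0L)
    step <- as.integer(round(t_s / dt)) + 1L
    by_step <- split(id, factor(step, levels = seq_len(n_steps)))
    spikes <- unname(lapply(by_step, function(v) sort(unname(v))))
  }
  structure(
    list(n_neurons = n_neurons, dt = dt, n_steps = n_steps, spikes = spikes),
    class = "spike_raster")
}
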