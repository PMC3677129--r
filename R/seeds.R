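# Seed-stream discipline: one root seed per experiment, per-purpose child
# seeds derived by fixed documented offsets so that connectivity, partition
# and spike generation are independently reproducible.

.seed_streams <- c(connectivity = 1L, partition = 2L, spikes = 3L)

#' Derive a purpose-specific child seed from a root seed
#'
#' Each module draws its random numbers from its own seeded stream so that,
#' for example, regenerating the spike trains does not perturb the network
#' connectivity. Child seeds are `(root + 7919 * stream_index) mod (2^31 - 1)`
#' with stream indices 1 (connectivity), 2 (partition), 3 (spikes); an extra
#' non-negative `offset` separates repeated uses within a stream (e.g. trials).
#'
#' @param root integer root seed.
#' @param stream one of `"connectivity"`, `"partition"`, `"spikes"`.
#' @param offset non-negative integer sub-stream offset (default 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "spikes")
derive_seed <- function(root, stream = c("connectivity", "partition", "spikes"),
                        offset = 0L) {
  stream <- match.arg(stream)
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root),
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  m <- 2147483647  # 2^31 - 1
  s <- (abs(root) + 7919 * .seed_streams[[stream]] + 104729 * offset) %% m
  as.integer(if (s == 0) 1 else s)
}
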