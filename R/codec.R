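# Spike packet codecs. A packet is one header word plus payload words.
# AER: header = S (number of firings), payload = the S local indices.
# Bit-packed: header = -1, payload = ceiling(N/32) words, one bit per
# output neuron (LSB-first within a word, words in ascending local-index
# order). The hybrid codec switches between the two per projection and per
# step at the pivot threshold F = P * N / 32.
#
# The header is one signed 32-bit word (not a byte: an AER count for large
# projections cannot fit in 8 bits); the sign alone dispatches the scheme.
# Payload words are 32-bit unsigned, carried in R as doubles because values
# >= 2^31 do not fit a signed R integer.

#' Number of bits per payload word
#' @export
WORD_BITS <- 32L

#' Pivot configuration for the hybrid codec
#'
#' The pivot multiplier P positions the AER-to-bit-packing transition
#' relative to the projection size: the threshold is `F = P * N / 32` spikes.
#' `P = 0` forces bit-packing for any non-empty firing set, `P = 1` switches
#' exactly at the packet-size crossover, and `P = 32` (so `F = N`) forces
#' AER always.
#'
#' @param P pivot multiplier in `[0, 32]`.
#' @return an object of class `pivot_config`.
#' @export
pivot_config <- function(P = 1) {
  stopifnot(is.numeric(P), length(P) == 1L, P >= 0, P <= WORD_BITS)
  structure(list(P = as.numeric(P)), class = "pivot_config")
}

#' Hybrid switching threshold F = P * N / 32
#'
#' Kept as an exact rational value: no rounding is applied before the
#' `S <= F` comparison, so e.g. `N = 2000, P = 1` gives `F = 62.5`, not 62
#' or 63.
#'
#' @param N projection size (>= 1).
#' @param pivot a [pivot_config()] or a bare numeric P.
#' @return the threshold F (numeric, possibly fractional).
#' @export
#' @examples
#' threshold(2000, 1)  # 62.5
#' threshold(576, 1)   # 18
threshold <- function(N, pivot = pivot_config(1)) {
  if (is.numeric(pivot)) pivot <- pivot_config(pivot)
  stopifnot(inherits(pivot, "pivot_config"), N >= 1)
  pivot$P * N / WORD_BITS
}

#' Per-step firing set of one projection
#'
#' @param fired_local 0-based local indices (positions in the projection's
#'   member list) that fired this step; must be unique and `< N`.
#' @param N projection size.
#' @return an object of class `step_spikes` with fields `fired_local`
#'   (sorted), `S` (count) and `N`.
#' @export
step_spikes <- function(fired_local, N) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  fired_local <- as.integer(fired_local)
  if (anyDuplicated(fired_local)) {
    stop("fired_local contains duplicate indices", call. = FALSE)
  }
  if (length(fired_local) &&
      (min(fired_local) < 0L || max(fired_local) >= N)) {
    stop("fired_local indices must lie in [0, N)", call. = FALSE)
  }
  structure(
    list(fired_local = sort(fired_local), S = length(fired_local), N = N),
    class = "step_spikes")
}

.new_packet <- function(header, payload, N) {
  structure(
    list(header = as.integer(header), payload = as.numeric(payload),
         N = as.integer(N),
         scheme = if (header >= 0L) "AER" else "BITPACKED"),
    class = "spike_packet")
}

#' @export
print.spike_packet <- function(x, ...) {
  cat("Spike packet [", x$scheme, "]: header", x$header, ",",
      length(x$payload), "payload words, N =", x$N, "\n")
  invisible(x)
}

#' Encode a firing set as an AER packet
#'
#' Header = S, payload = the S fired local indices in ascending order; the
#' packet grows linearly with activity.
#'
#' @param spikes a [step_spikes()].
#' @return a `spike_packet`.
#' @export
encode_aer <- function(spikes) {
  stopifnot(inherits(spikes, "step_spikes"))
  if (spikes$S > .Machine$integer.max) {
    stop("firing count exceeds header word capacity", call. = FALSE)
  }
  .new_packet(spikes$S, as.numeric(spikes$fired_local), spikes$N)
}

#' Encode a firing set as a bit-packed packet
#'
#' Header = -1; payload is `ceiling(N / 32)` words in which bit `k` of word
#' `j` (LSB-first) is set iff local index `32 j + k` fired. The payload size
#' depends only on N, never on how many neurons fired — the rate-independent
#' scheme.
#'
#' @param spikes a [step_spikes()].
#' @return a `spike_packet`.
#' @export
encode_bitpacked <- function(spikes) {
  stopifnot(inherits(spikes, "step_spikes"))
  n_words <- ceiling(spikes$N / WORD_BITS)
  payload <- numeric(n_words)
  if (spikes$S > 0L) {
    word <- spikes$fired_local %/% WORD_BITS
    bit <- spikes$fired_local %% WORD_BITS
    add <- rowsum(2^bit, word)  # each index unique => each bit set once
    payload[as.integer(rownames(add)) + 1L] <- as.numeric(add)
  }
  .new_packet(-1L, payload, spikes$N)
}

#' Encode with the hybrid scheme
#'
#' Uses AER when `S <= F` and bit-packing when `S > F`, with
#' `F = P * N / 32` from [threshold()]. At `P = 1` the chosen packet is
#' never larger than the better of the two pure schemes, giving the
#' deterministic upper bound of `ceiling(N/32)` payload words per step.
#'
#' @param spikes a [step_spikes()].
#' @param pivot a [pivot_config()] or bare numeric P.
#' @return a `spike_packet`.
#' @export
#' @examples
#' pm <- step_spikes(0:71, N = 2000)
#' encode_hybrid(pm, 1)  # 72 > F = 62.5: bit-packed, 63 payload words
encode_hybrid <- function(spikes, pivot = pivot_config(1)) {
  stopifnot(inherits(spikes, "step_spikes"))
  if (spikes$S <= threshold(spikes$N, pivot)) {
    encode_aer(spikes)
  } else {
    encode_bitpacked(spikes)
  }
}

#' Decode a spike packet
#'
#' The scheme is dispatched on the header sign alone: a non-negative header
#' is an AER firing count, a negative header marks a bit-packed payload.
#' Malformed packets (payload length inconsistent with the header or with
#' `ceiling(N/32)`, indices or set bits at positions `>= N`) are rejected.
#'
#' @param packet a `spike_packet`.
#' @param N projection size the packet was encoded against.
#' @return a [step_spikes()] with the recovered firing set.
#' @export
decode <- function(packet, N) {
  stopifnot(inherits(packet, "spike_packet"))
  N <- as.integer(N)
  if (packet$header >= 0L) {
    if (length(packet$payload) != packet$header) {
      stop("malformed AER packet: header ", packet$header, " but ",
           length(packet$payload), " payload words", call. = FALSE)
    }
    idx <- as.integer(packet$payload)
    if (length(idx) && max(idx) >= N) {
      stop("malformed AER packet: local index >= N", call. = FALSE)
    }
    step_spikes(idx, N)
  } else {
    n_words <- ceiling(N / WORD_BITS)
    if (length(packet$payload) != n_words) {
      stop("malformed bit-packed packet: expected ", n_words,
           " payload words for N = ", N, ", got ", length(packet$payload),
           call. = FALSE)
    }
    fired <- integer(0)
    for (j in seq_len(n_words)) {
      w <- packet$payload[j]
      if (w > 0) {
        bits <- which(floor(w / 2^(0:(WORD_BITS - 1L))) %% 2 == 1) - 1L
        fired <- c(fired, (j - 1L) * WORD_BITS + bits)
      }
    }
    if (length(fired) && max(fired) >= N) {
      stop("malformed bit-packed packet: set bit at position >= N",
           call. = FALSE)
    }
    step_spikes(fired, N)
  }
}

#' Payload word count of a packet
#'
#' The header word is excluded, matching the packet-size comparison in which
#' a 2000-neuron projection with 72 firings costs 63 bit-packed words
#' against 72 AER words. Whole-message accounting (header included) lives in
#' the exchange layer's cost records.
#'
#' @param packet a `spike_packet`.
#' @return integer word count.
#' @export
packet_payload_words <- function(packet) {
  stopifnot(inherits(packet, "spike_packet"))
  length(packet$payload)
}

# ---- binary wire format -------------------------------------------------
# Little-endian stream of 32-bit words: for each packet, one signed header
# word followed by its payload words (unsigned). AER payload length is given
# by the header; bit-packed payload length is ceiling(N/32), so a reader
# needs the projection size N of the stream.

.unsigned_to_signed32 <- function(x) {
  as.integer(ifelse(x >= 2^31, x - 2^32, x))
}

.signed_to_unsigned32 <- function(x) {
  y <- as.numeric(x)
  ifelse(y < 0, y + 2^32, y)
}

#' Write packets to a little-endian binary stream
#'
#' @param packets list of `spike_packet` objects (one projection's stream,
#'   in step order).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_packets <- function(packets, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (pk in packets) {
    stopifnot(inherits(pk, "spike_packet"))
    writeBin(pk$header, con, size = 4L, endian = "little")
    if (length(pk$payload)) {
      writeBin(.unsigned_to_signed32(pk$payload), con, size = 4L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read packets from a stream written by [write_packets()]
#'
#' @param path binary file.
#' @param N projection size of the stream (fixes the bit-packed payload
#'   length).
#' @return list of `spike_packet` objects.
#' @export
read_packets <- function(path, N) {
  N <- as.integer(N)
  con <- file(path, "rb")
  on.exit(close(con))
  packets <- list()
  repeat {
    header <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(header) == 0L) break
    n_words <- if (header >= 0L) header else ceiling(N / WORD_BITS)
    payload <- integer(0)
    if (n_words > 0L) {
      payload <- readBin(con, "integer", n = n_words, size = 4L,
                         endian = "little")
      if (length(payload) != n_words) {
        stop("truncated packet stream", call. = FALSE)
      }
    }
    packets[[length(packets) + 1L]] <-
      .new_packet(header, .signed_to_unsigned32(payload), N)
  }
  packets
}
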