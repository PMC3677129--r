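# Desk-scale spike exchange between simulated compute nodes. Three
# mechanisms (blocking point-to-point, non-blocking point-to-point, and a
# variable-size collective) are exposed through one contract: in every
# iteration each node sends exactly one packet along each of its outgoing
# projections and receives exactly one along each incoming projection.
# On the loopback backend the three modes are semantically identical (they
# differ only in real-transport scheduling); communication cost is accounted
# in 32-bit words (header + payload) and bytes, the deterministic proxy for
# wall-clock communication time, which is hardware-bound.

#' Transport configuration
#'
#' @param mode `"blocking"` or `"nonblocking"` point-to-point, or
#'   `"collective"` (the variable-size all-to-all, `alltoallv`; the alias
#'   `"alltoallv"` is accepted).
#' @param backend `"loopback"` (in-process, deterministic; the only backend
#'   available here). An MPI process-per-node mapping is documented in the
#'   package vignette but not bundled.
#' @return an object of class `spike_transport`.
#' @export
transport <- function(mode = c("blocking", "nonblocking", "collective",
                               "alltoallv"),
                      backend = "loopback") {
  mode <- match.arg(mode)
  if (mode == "alltoallv") mode <- "collective"
  backend <- match.arg(backend, c("loopback", "mpi"))
  if (backend == "mpi") {
    stop("the MPI backend is not bundled with this package; ",
         "use backend = \"loopback\"", call. = FALSE)
  }
  structure(list(mode = mode, backend = backend), class = "spike_transport")
}

#' Per-iteration communication cost record
#'
#' @param per_pair named numeric vector of whole-message word counts
#'   (header + payload), one entry per `"src->dst"` projection pair.
#' @param iteration iteration index.
#' @return an object of class `cost_record` with `per_pair`, `total_words`,
#'   `total_bytes` (= 4 x words) and `max_pair_words`.
#' @export
cost_record <- function(per_pair, iteration = 0L) {
  per_pair <- unlist(per_pair)
  total <- if (length(per_pair)) sum(per_pair) else 0
  structure(
    list(iteration = as.integer(iteration),
         per_pair = per_pair,
         total_words = total,
         total_bytes = 4 * total,
         max_pair_words = if (length(per_pair)) max(per_pair) else 0),
    class = "cost_record")
}

#' @export
print.cost_record <- function(x, ...) {
  cat("Cost record (iteration", x$iteration, "):", length(x$per_pair),
      "pairs,", x$total_words, "words,", x$total_bytes, "bytes\n")
  invisible(x)
}

#' Exchange one iteration's packets between nodes
#'
#' Validates the protocol (exactly one packet per existing projection pair,
#' no extras), delivers every packet to its destination node, and accounts
#' the cost. Delivery content is independent of mode: decoded spike sets are
#' identical under blocking, non-blocking and collective exchange on the
#' loopback backend, which is the contract real transports must also honour.
#'
#' @param part an `snn_partition`.
#' @param per_pair_packets named list of `spike_packet`s keyed `"src->dst"`,
#'   one per projection pair of `part`.
#' @param transport a [transport()].
#' @param iteration iteration index recorded in the cost record.
#' @return list with `delivered` (per destination node id as character, a
#'   named list of packets keyed by source node) and `cost` (a
#'   [cost_record()]).
#' @export
exchange_step <- function(part, per_pair_packets, transport = NULL,
                          iteration = 0L) {
  stopifnot(inherits(part, "snn_partition"))
  if (is.null(transport)) transport <- hybridspike::transport("nonblocking")
  stopifnot(inherits(transport, "spike_transport"))
  want <- names(part$projections)
  have <- names(per_pair_packets)
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra)) {
    stop("protocol violation: ",
         if (length(missing)) paste("missing packet for",
                                    paste(missing, collapse = ", ")) else "",
         if (length(missing) && length(extra)) "; " else "",
         if (length(extra)) paste("unexpected packet for",
                                  paste(extra, collapse = ", ")) else "",
         call. = FALSE)
  }
  delivered <- vector("list", part$n_nodes)
  names(delivered) <- as.character(0:(part$n_nodes - 1L))
  for (b in seq_len(part$n_nodes)) delivered[[b]] <- list()
  per_pair <- numeric(length(want))
  names(per_pair) <- want
  for (key in want) {
    pk <- per_pair_packets[[key]]
    stopifnot(inherits(pk, "spike_packet"))
    pm <- part$projections[[key]]
    delivered[[as.character(pm$dst_node)]][[as.character(pm$src_node)]] <- pk
    per_pair[[key]] <- 1 + length(pk$payload)  # header word + payload
  }
  list(delivered = delivered, cost = cost_record(per_pair, iteration))
}

#' Run one full simulation iteration over a partition
#'
#' Builds the per-projection firing sets from the global ids that fired this
#' step, encodes each with the requested codec, exchanges the packets,
#' decodes them at the destinations and verifies spike conservation (every
#' decoded set equals the encoded one: no loss, no duplication).
#'
#' @param part an `snn_partition`.
#' @param fired integer vector of global neuron ids that fired this step.
#' @param codec_mode `"aer"`, `"bitpacked"` or `"hybrid"`.
#' @param pivot pivot multiplier or [pivot_config()] (hybrid mode only).
#' @param transport a [transport()].
#' @param iteration iteration index for the cost record.
#' @param return_delivery if `TRUE`, attach the decoded remote spike sets
#'   (`delivered_global`, per destination node: sorted global ids of remote
#'   neurons whose spike arrived there).
#' @return a [cost_record()]; with `return_delivery = TRUE`, a list
#'   `(cost, delivered_global)`.
#' @export
run_iteration <- function(part, fired, codec_mode = c("hybrid", "aer",
                                                      "bitpacked"),
                          pivot = 1, transport = NULL, iteration = 0L,
                          return_delivery = FALSE) {
  stopifnot(inherits(part, "snn_partition"))
  codec_mode <- match.arg(codec_mode)
  fired <- as.integer(fired)
  packets <- vector("list", length(part$projections))
  names(packets) <- names(part$projections)
  spikes_by_pair <- packets
  for (key in names(part$projections)) {
    pm <- part$projections[[key]]
    loc <- projection_local_index(pm, fired)
    sp <- step_spikes(loc[!is.na(loc)], pm$N)
    spikes_by_pair[[key]] <- sp
    packets[[key]] <- switch(codec_mode,
      aer = encode_aer(sp),
      bitpacked = encode_bitpacked(sp),
      hybrid = encode_hybrid(sp, pivot))
  }
  ex <- exchange_step(part, packets, transport, iteration)
  delivered_global <- vector("list", part$n_nodes)
  names(delivered_global) <- as.character(0:(part$n_nodes - 1L))
  for (dst in names(ex$delivered)) {
    ids <- integer(0)
    for (src in names(ex$delivered[[dst]])) {
      pm <- part$projections[[.pair_key(src, dst)]]
      dec <- decode(ex$delivered[[dst]][[src]], pm$N)
      if (!identical(dec$fired_local,
                     spikes_by_pair[[.pair_key(src, dst)]]$fired_local)) {
        stop("spike conservation violated on pair ", .pair_key(src, dst),
             call. = FALSE)
      }
      ids <- c(ids, pm$members[dec$fired_local + 1L])
    }
    delivered_global[[dst]] <- sort(ids)
  }
  if (return_delivery) {
    list(cost = ex$cost, delivered_global = delivered_global)
  } else {
    ex$cost
  }
}

#' Stream cost records as JSON lines
#'
#' One JSON object per iteration with `iteration`, `total_words`,
#' `total_bytes`, `max_pair_words` and the `per_pair` map.
#'
#' @param records list of [cost_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cost_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    stopifnot(inherits(r, "cost_record"))
    writeLines(jsonlite::toJSON(
      list(iteration = r$iteration, total_words = r$total_words,
           total_bytes = r$total_bytes, max_pair_words = r$max_pair_words,
           per_pair = as.list(r$per_pair)),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
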