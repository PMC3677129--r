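# Random network generation, even partitioning across simulated compute
# nodes, and the projection maps / dummy-neuron registries that the spike
# codecs operate on. All neuron and node ids are global and 0-based.

#' Generate a random spiking network
#'
#' Each neuron receives exactly `n_connections` outgoing connections drawn
#' uniformly without replacement from all other neurons (no self-connections,
#' no duplicate targets for a given source). Connectivity is drawn from the
#' `"connectivity"` child stream of `seed`, so the same `(n_neurons,
#' n_connections, seed)` triple always yields the identical network.
#'
#' @param n_neurons number of neurons (>= 2).
#' @param n_connections outgoing connections per neuron
#'   (`<= n_neurons - 1`).
#' @param seed integer root seed.
#' @return an object of class `snn_network` with fields `n_neurons`,
#'   `n_connections_per_neuron` and `connections`, a two-column integer
#'   matrix of 0-based `(pre, post)` pairs ordered by `pre`.
#' @export
#' @examples
#' net <- generate_network(100, 10, seed = 7)
#' head(net$connections)
generate_network <- function(n_neurons, n_connections, seed) {
  stopifnot(is.numeric(n_neurons), n_neurons >= 2,
            is.numeric(n_connections), n_connections >= 1)
  n_neurons <- as.integer(n_neurons)
  n_connections <- as.integer(n_connections)
  if (n_connections > n_neurons - 1L) {
    stop("n_connections must be <= n_neurons - 1: cannot sample ",
         n_connections, " distinct non-self targets among ", n_neurons,
         " neurons", call. = FALSE)
  }
  set.seed(derive_seed(seed, "connectivity"))
  pre <- rep(0:(n_neurons - 1L), each = n_connections)
  post <- integer(length(pre))
  idx <- 1L
  for (p in 0:(n_neurons - 1L)) {
    # sample over 0..n-2 then shift values >= p by one to skip self
    tgt <- sample.int(n_neurons - 1L, n_connections) - 1L
    tgt <- ifelse(tgt >= p, tgt + 1L, tgt)
    post[idx:(idx + n_connections - 1L)] <- tgt
    idx <- idx + n_connections
  }
  structure(
    list(n_neurons = n_neurons,
         n_connections_per_neuron = n_connections,
         connections = cbind(pre = pre, post = post)),
    class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("Random spiking network:", x$n_neurons, "neurons,",
      x$n_connections_per_neuron, "connections/neuron,",
      nrow(x$connections), "connections total\n")
  invisible(x)
}

#' Construct a projection map
#'
#' A projection map records, for an ordered pair of compute nodes `(A, B)`,
#' the set of A's neurons with at least one synapse onto a neuron owned by B.
#' Its cardinality `N` is the quantity that drives packet sizing, and the
#' 0-based ascending order of `members` fixes the bit-position convention
#' used by the bit-packed codec.
#'
#' @param src_node,dst_node 0-based node ids.
#' @param members global neuron ids projecting from `src_node` to
#'   `dst_node`; stored sorted ascending, duplicates removed.
#' @return an object of class `projection_map` with fields `src_node`,
#'   `dst_node`, `members`, `N`.
#' @export
projection_map <- function(src_node, dst_node, members) {
  stopifnot(length(members) >= 1L, all(members >= 0))
  members <- sort(unique(as.integer(members)))
  structure(
    list(src_node = as.integer(src_node), dst_node = as.integer(dst_node),
         members = members, N = length(members)),
    class = "projection_map")
}

#' Map global neuron ids to local projection indices
#'
#' @param pm a [projection_map()].
#' @param ids global neuron ids.
#' @return 0-based positions in `pm$members`; `NA` for ids not in the map.
#' @export
projection_local_index <- function(pm, ids) {
  match(as.integer(ids), pm$members) - 1L
}

.pair_key <- function(src, dst) paste0(src, "->", dst)

#' Assemble a network partition from explicit ownership and projections
#'
#' Low-level constructor used both by [partition_network()] and for
#' hand-built fixtures. Ownership must be balanced (every node owns the same
#' number of neurons); the dummy-neuron registry of each node is derived as
#' the union of the member sets of its incoming projections.
#'
#' @param owner integer vector, `owner[i]` = 0-based node owning neuron
#'   `i - 1`.
#' @param n_nodes number of compute nodes.
#' @param projections list of [projection_map()] objects (src != dst, each
#'   member owned by its source node).
#' @return an object of class `snn_partition`.
#' @export
network_partition <- function(owner, n_nodes, projections = list()) {
  owner <- as.integer(owner)
  n_nodes <- as.integer(n_nodes)
  n_neurons <- length(owner)
  stopifnot(n_nodes >= 1L, all(owner >= 0L), all(owner < n_nodes))
  counts <- tabulate(owner + 1L, nbins = n_nodes)
  if (length(unique(counts)) != 1L) {
    stop("unbalanced ownership: each node must own the same number of neurons",
         call. = FALSE)
  }
  keys <- character(length(projections))
  for (i in seq_along(projections)) {
    pm <- projections[[i]]
    stopifnot(inherits(pm, "projection_map"))
    if (pm$src_node == pm$dst_node) {
      stop("projection maps exist only between distinct nodes", call. = FALSE)
    }
    if (any(owner[pm$members + 1L] != pm$src_node)) {
      stop("projection ", .pair_key(pm$src_node, pm$dst_node),
           " lists members not owned by its source node", call. = FALSE)
    }
    keys[i] <- .pair_key(pm$src_node, pm$dst_node)
  }
  if (anyDuplicated(keys)) stop("duplicate projection pair", call. = FALSE)
  names(projections) <- keys

  dummy_registry <- vector("list", n_nodes)
  names(dummy_registry) <- as.character(0:(n_nodes - 1L))
  for (b in 0:(n_nodes - 1L)) dummy_registry[[b + 1L]] <- integer(0)
  for (pm in projections) {
    b <- pm$dst_node + 1L
    dummy_registry[[b]] <- sort(union(dummy_registry[[b]], pm$members))
  }
  structure(
    list(n_nodes = n_nodes, n_neurons = n_neurons, owner = owner,
         projections = projections, dummy_registry = dummy_registry),
    class = "snn_partition")
}

#' Partition a network evenly across compute nodes
#'
#' Neuron ids are shuffled with the `"partition"` child stream of `seed` and
#' assigned to nodes in contiguous equal blocks, so every node simulates the
#' same number of neurons. Projection maps and dummy-neuron registries are
#' then derived from the connection list: a neuron appears in the projection
#' map `(A, B)` once if it is owned by A and has at least one target owned
#' by B, no matter how many synapses it has there (a remote spike reaches a
#' node at most once and is relayed locally by the dummy neuron).
#'
#' @param net an [generate_network()] result.
#' @param n_nodes number of compute nodes; must divide `net$n_neurons`.
#' @param seed integer root seed.
#' @return an `snn_partition` (see [network_partition()]).
#' @export
partition_network <- function(net, n_nodes, seed) {
  stopifnot(inherits(net, "snn_network"))
  n_nodes <- as.integer(n_nodes)
  if (net$n_neurons %% n_nodes != 0L) {
    stop("n_nodes (", n_nodes, ") must divide n_neurons (", net$n_neurons,
         "): nodes simulate equal numbers of neurons", call. = FALSE)
  }
  set.seed(derive_seed(seed, "partition"))
  perm <- sample.int(net$n_neurons) - 1L  # perm[k] = neuron placed at slot k-1
  block <- net$n_neurons %/% n_nodes
  owner <- integer(net$n_neurons)
  owner[perm + 1L] <- rep(0:(n_nodes - 1L), each = block)

  pre <- net$connections[, "pre"]
  post <- net$connections[, "post"]
  src <- owner[pre + 1L]
  dst <- owner[post + 1L]
  cross <- src != dst
  projections <- list()
  if (any(cross)) {
    key <- .pair_key(src[cross], dst[cross])
    by_pair <- split(data.frame(pre = pre[cross], src = src[cross],
                                dst = dst[cross]), key)
    projections <- lapply(by_pair, function(d) {
      projection_map(d$src[1L], d$dst[1L], unique(d$pre))
    })
    names(projections) <- NULL
  }
  network_partition(owner, n_nodes, projections)
}

#' @export
print.snn_partition <- function(x, ...) {
  cat("Network partition:", x$n_neurons, "neurons over", x$n_nodes,
      "nodes (", x$n_neurons %/% x$n_nodes, "per node ),",
      length(x$projections), "cross-node projections\n")
  invisible(x)
}

#' Number of dummy neurons hosted on a node
#'
#' Dummy neurons are local mirrors of remote pre-synaptic neurons: node B
#' hosts one for every distinct remote neuron with at least one synapse onto
#' a B-owned neuron, i.e. the union of the member sets of B's incoming
#' projections.
#'
#' @param part an `snn_partition`.
#' @param node 0-based node id.
#' @return integer count.
#' @export
dummy_neuron_count <- function(part, node) {
  stopifnot(inherits(part, "snn_partition"))
  node <- as.integer(node)
  if (node < 0L || node >= part$n_nodes) {
    stop("unknown node id ", node, " (partition has ", part$n_nodes,
         " nodes)", call. = FALSE)
  }
  length(part$dummy_registry[[node + 1L]])
}

#' Save a partition to JSON
#'
#' The layout is an object with `n_nodes`, `n_neurons`, the `owner` array and
#' a `projections` array of `{src, dst, members}` records. A path ending in
#' `.gz` writes the gzip-compressed variant.
#'
#' @param part an `snn_partition`.
#' @param path output file; `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
save_partition <- function(part, path) {
  stopifnot(inherits(part, "snn_partition"))
  obj <- list(
    n_nodes = part$n_nodes,
    n_neurons = part$n_neurons,
    owner = part$owner,
    projections = lapply(unname(part$projections), function(pm) {
      list(src = pm$src_node, dst = pm$dst_node, members = pm$members)
    }))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Load a partition saved by [save_partition()]
#'
#' @param path file written by [save_partition()]; `.gz` handled
#'   transparently.
#' @return an `snn_partition`.
#' @export
load_partition <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  obj <- jsonlite::fromJSON(paste(readLines(con), collapse = ""),
                            simplifyDataFrame = FALSE)
  projections <- lapply(obj$projections, function(p) {
    projection_map(p$src, p$dst, unlist(p$members))
  })
  network_partition(unlist(obj$owner), obj$n_nodes, projections)
}
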