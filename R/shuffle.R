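#' Degree-preserving randomization of a traffic network
#'
#' Generates the shuffled null used to benchmark motif and chain
#' statistics. Vesicle edges are removed. The targets of the remaining
#' edges are then randomly swapped, only ever between two maturation edges
#' or between two creation edges. A candidate swap is rejected if a self
#' edge would be lost, a self edge would be created, or multiple edges of
#' the same type would arise between the same source and target. The
#' procedure therefore preserves, per node and per edge type, the in- and
#' out-degrees and the exact self-edge set.
#'
#' The attempt budget is `swaps_per_edge` times the edge count of each
#' type; rejected swaps consume budget (standard edge-swap MCMC; the
#' default budget is ample for the small networks produced by the sweep).
#'
#' @param net a `traffic_network`.
#' @param swaps_per_edge attempted swaps per edge of each type.
#' @param seed optional integer passed to `set.seed()`.
#' @return a `traffic_network` with shuffled creation/maturation edges, no
#'   vesicle edges, and attribute `shuffled = TRUE`. Chain and motif
#'   analyses apply unchanged; `node_next` no longer reflects Boolean
#'   updates and dissipation flags are not meaningful on shuffled
#'   networks.
#' @export
shuffle_network <- function(net, swaps_per_edge = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- net
  out$vesicle_edges <- data.frame(from = integer(0), to = integer(0))
  out$vesicle_edges$vesicles <- list()
  out$creation_edges <- shuffle_edge_targets(net$creation_edges, swaps_per_edge)
  out$maturation_edges <- shuffle_edge_targets(net$maturation_edges, swaps_per_edge)
  # keep dissipation information only where the maturation structure is
  # untouched; flag provenance
  attr(out, "shuffled") <- TRUE
  out
}

# swap edge targets within one edge type under the rejection rules
shuffle_edge_targets <- function(edges, swaps_per_edge) {
  m <- nrow(edges)
  if (m < 2L) return(edges)
  from <- edges$from
  to <- edges$to
  attempts <- as.integer(swaps_per_edge) * m
  for (s in seq_len(attempts)) {
    pick <- sample.int(m, 2L)
    i <- pick[1L]; j <- pick[2L]
    # self edges are frozen: swapping one would lose it
    if (from[i] == to[i] || from[j] == to[j]) next
    # swap must not create a self edge
    if (from[i] == to[j] || from[j] == to[i]) next
    # no duplicate (source, target) within the type
    if (any(from == from[i] & to == to[j])) next
    if (any(from == from[j] & to == to[i])) next
    tmp <- to[i]; to[i] <- to[j]; to[j] <- tmp
  }
  out <- edges
  out$to <- to
  out
}
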