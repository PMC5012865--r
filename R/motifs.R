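# Three-compartment motifs over the creation + maturation edge types.
#
# A labeled motif on nodes {1,2,3} is encoded as an 18-bit integer: bit
# position (t - 1)*9 + (a - 1)*3 + b (0-based) holds edge type t (1 =
# creation, 2 = maturation) from node a to node b; self-edges are allowed.
# A motif is connected when the undirected union of both edge types links
# all three nodes, i.e. at least two of the three distinct node pairs are
# covered (self-edges do not connect). Canonical form = minimum code over
# the 6 node permutations.

motif_pairs <- function() {
  cbind(a = rep(1:3, each = 3), b = rep(1:3, times = 3))
}

motif_perms <- function() {
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# bit position (1-based) of (type, a, b)
motif_bit <- function(type, a, b) (type - 1L) * 9L + (a - 1L) * 3L + b

#' Canonical form of a labeled 3-node motif code
#'
#' @param code 18-bit integer code(s) of labeled motifs.
#' @return integer vector of canonical codes (minimum over the 6 node
#'   permutations).
#' @export
canonical_motif <- function(code) {
  code <- as.integer(code)
  pairs <- motif_pairs()
  best <- rep(.Machine$integer.max, length(code))
  for (perm in motif_perms()) {
    new <- integer(length(code))
    for (t in 1:2) {
      for (p in seq_len(nrow(pairs))) {
        a <- pairs[p, 1L]; b <- pairs[p, 2L]
        src <- motif_bit(t, a, b)
        dst <- motif_bit(t, perm[a], perm[b])
        bit <- bitwAnd(bitwShiftR(code, src - 1L), 1L)
        new <- new + bit * 2L^(dst - 1L)
      }
    }
    best <- pmin(best, new)
  }
  best
}

#' Is a labeled 3-node motif code weakly connected?
#'
#' @param code 18-bit integer code(s).
#' @return logical vector.
#' @export
motif_connected <- function(code) {
  code <- as.integer(code)
  pair_covered <- function(a, b) {
    m <- rep(FALSE, length(code))
    for (t in 1:2) {
      for (bit in c(motif_bit(t, a, b), motif_bit(t, b, a))) {
        m <- m | bitwAnd(bitwShiftR(code, bit - 1L), 1L) == 1L
      }
    }
    m
  }
  (pair_covered(1L, 2L) + pair_covered(1L, 3L) + pair_covered(2L, 3L)) >= 2L
}

#' Exhaustive catalog of connected three-compartment motifs
#'
#' Enumerates all `2^18 = 262144` labeled 3-node directed graphs over the
#' two edge types (creation, maturation) including self-loops, keeps those
#' weakly connected over the union of edge types, and collapses them into
#' isomorphism classes under the 6 node permutations. The catalog is
#' deterministic: class index 1 corresponds to the smallest canonical
#' code.
#'
#' @return an object of class `motif_catalog`: data.frame with columns
#'   `index` and `code` (canonical 18-bit code), with a lookup environment
#'   attached for constant-time code-to-index mapping.
#' @examples
#' \donttest{
#' cat3 <- motif_catalog()
#' nrow(cat3)  # number of connected motif classes
#' }
#' @export
motif_catalog <- function() {
  codes <- 0:(2L^18L - 1L)
  keep <- motif_connected(codes)
  canon <- canonical_motif(codes[keep])
  classes <- sort(unique(canon))
  catalog <- data.frame(index = seq_along(classes), code = classes)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(classes)) {
    assign(as.character(classes[k]), k, envir = lookup)
  }
  structure(catalog, lookup = lookup, class = c("motif_catalog", "data.frame"))
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("<motif_catalog> %d connected 3-node motif classes (2 edge types, self-loops allowed)\n",
              nrow(x)))
  invisible(x)
}

#' Encode an induced 3-node subgraph as a labeled motif code
#'
#' @param cre,mat 3x3 logical adjacency matrices of creation and
#'   maturation edges on the chosen node triple (row = source).
#' @return integer 18-bit code.
#' @export
encode_motif <- function(cre, mat) {
  code <- 0L
  for (a in 1:3) for (b in 1:3) {
    if (cre[a, b]) code <- code + 2L^(motif_bit(1L, a, b) - 1L)
    if (mat[a, b]) code <- code + 2L^(motif_bit(2L, a, b) - 1L)
  }
  code
}

#' Count motif instances in a traffic network
#'
#' Takes every 3-subset of compartments, forms the induced subgraph on the
#' creation and maturation edges, and, if it is weakly connected, tallies
#' its isomorphism class. Vesicle edges are ignored, matching the motif
#' definition. Counts are invariant under node relabeling.
#'
#' @param net a `traffic_network` (or a list with `nodes`,
#'   `creation_edges`, `maturation_edges`).
#' @param catalog a [motif_catalog()].
#' @return integer vector of counts indexed by catalog class (named by
#'   class index); only non-zero entries are returned.
#' @export
count_motifs <- function(net, catalog) {
  nodes <- net$nodes
  n <- length(nodes)
  counts <- integer(0)
  if (n < 3L) return(counts)
  idx <- function(v) match(v, nodes)
  cre <- matrix(FALSE, n, n)
  if (nrow(net$creation_edges)) {
    cre[cbind(idx(net$creation_edges$from), idx(net$creation_edges$to))] <- TRUE
  }
  mat <- matrix(FALSE, n, n)
  if (nrow(net$maturation_edges)) {
    mat[cbind(idx(net$maturation_edges$from), idx(net$maturation_edges$to))] <- TRUE
  }
  lookup <- attr(catalog, "lookup")
  triples <- utils::combn(n, 3L)
  tallies <- new.env(hash = TRUE, parent = emptyenv())
  for (col in seq_len(ncol(triples))) {
    tr <- triples[, col]
    code <- encode_motif(cre[tr, tr], mat[tr, tr])
    if (!motif_connected(code)) next
    cls <- lookup[[as.character(canonical_motif(code))]]
    key <- as.character(cls)
    prev <- tallies[[key]]
    tallies[[key]] <- if (is.null(prev)) 1L else prev + 1L
  }
  keys <- ls(tallies)
  counts <- vapply(keys, function(k) tallies[[k]], integer(1))
  names(counts) <- keys
  counts[order(as.integer(keys))]
}

#' Aggregate motif counts over a collection of networks
#'
#' @param networks list of `traffic_network` objects.
#' @param catalog a [motif_catalog()].
#' @return data.frame with one row per motif class observed: `index`,
#'   `total` (copies summed over networks) and `n_networks` (networks
#'   containing at least one copy).
#' @export
motif_census <- function(networks, catalog) {
  total <- new.env(hash = TRUE, parent = emptyenv())
  presence <- new.env(hash = TRUE, parent = emptyenv())
  for (net in networks) {
    cm <- count_motifs(net, catalog)
    for (k in names(cm)) {
      prev <- total[[k]]
      total[[k]] <- if (is.null(prev)) cm[[k]] else prev + cm[[k]]
      prev <- presence[[k]]
      presence[[k]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  keys <- ls(total)
  out <- data.frame(
    index = as.integer(keys),
    total = vapply(keys, function(k) total[[k]], integer(1)),
    n_networks = vapply(keys, function(k) presence[[k]], integer(1))
  )
  out <- out[order(-out$n_networks, -out$total), , drop = FALSE]
  rownames(out) <- NULL
  out
}
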