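#' Layout energy of compartment positions
#'
#' The energy is a sum over ordered pairs of distinct compartments
#' `i != j` of `1 / s_ij + (a0 + a_ij) * s_ij^2`, where `s_ij` is the
#' Euclidean distance and `a_ij = 1` iff a vesicle edge goes from `i` to
#' `j`. Compartments act as repelling charges (the `1/s` term spreads them
#' uniformly) while vesicle fluxes act as attractive springs (the `s^2`
#' term shortens trafficked pairs); `a0` sets the baseline spring that
#' confines the cloud. A symmetric pair trafficked in both directions
#' contributes `a0 + 1` twice.
#'
#' @param positions numeric `n x 2` matrix of compartment coordinates.
#' @param adjacency `n x n` logical/0-1 matrix of directed vesicle edges
#'   (self-edges ignored).
#' @param a0 baseline spring constant (default 0.1).
#' @return scalar energy; errors on coincident points.
#' @export
layout_energy <- function(positions, adjacency, a0 = 0.1) {
  n <- nrow(positions)
  if (n < 2L) return(0)
  d <- as.matrix(stats::dist(positions))
  off <- upper.tri(d) | lower.tri(d)
  if (any(d[off] == 0)) stop("coincident compartment positions: energy is singular")
  K <- a0 + (adjacency != 0)
  diag(K) <- 0
  sum(1 / d[off]) + sum((K * d^2)[off])
}

# gradient of layout_energy with respect to the flattened positions
layout_gradient <- function(positions, adjacency, a0 = 0.1) {
  n <- nrow(positions)
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  K <- a0 + (adjacency != 0)
  # coefficient on u_ij = r_i - r_j for the gradient at i: both ordered
  # terms involve s_ij, so the repulsion doubles and the springs couple as
  # K_ij + K_ji
  coef <- 2 * (K + t(K)) - 2 / d^3
  diag(coef) <- 0
  gx <- rowSums(coef * outer(positions[, 1L], positions[, 1L], "-"))
  gy <- rowSums(coef * outer(positions[, 2L], positions[, 2L], "-"))
  cbind(gx, gy)
}

#' Vesicle-edge adjacency matrix of a network
#' @param net a `traffic_network`.
#' @return `n x n` logical matrix aligned with `net$nodes`.
#' @export
vesicle_adjacency <- function(net) {
  n <- length(net$nodes)
  adj <- matrix(FALSE, n, n)
  if (nrow(net$vesicle_edges)) {
    adj[cbind(match(net$vesicle_edges$from, net$nodes),
              match(net$vesicle_edges$to, net$nodes))] <- TRUE
  }
  diag(adj) <- FALSE
  adj
}

#' Minimum-energy 2-D placement of compartments
#'
#' Minimizes [layout_energy()] by quasi-Newton (BFGS) descent with
#' analytic gradients from multiple random starting configurations,
#' keeping the best local minimum. Only vesicle edges enter the
#' optimization; maturation and creation edges are ignored, so any
#' spatial stacking of maturation chains in the result is an emergent
#' property of the vesicle flows. The optimum is defined up to rigid
#' motions (translation/rotation/reflection).
#'
#' @param net a `traffic_network`, or an adjacency matrix of vesicle
#'   edges.
#' @param restarts number of random initial configurations (default 10).
#' @param a0 baseline spring constant.
#' @param seed optional integer passed to `set.seed()`.
#' @param maxit BFGS iteration cap per start.
#' @return list of class `traffic_layout` with `positions` (`n x 2`),
#'   `energy`, `converged` (best start hit the gradient tolerance) and
#'   `nodes`.
#' @export
optimize_layout <- function(net, restarts = 10L, a0 = 0.1, seed = NULL,
                            maxit = 500L) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(net, "traffic_network")) {
    adj <- vesicle_adjacency(net)
    nodes <- net$nodes
  } else {
    adj <- net != 0
    nodes <- seq_len(nrow(adj))
  }
  n <- nrow(adj)
  stopifnot(n >= 2L)
  fn <- function(par) layout_energy(matrix(par, n, 2L), adj, a0)
  gr <- function(par) as.vector(layout_gradient(matrix(par, n, 2L), adj, a0))
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- stats::rnorm(2L * n, sd = max(1, sqrt(n) / 2))
    fit <- stats::optim(start, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(
    list(positions = matrix(best$par, n, 2L), energy = best$value,
         converged = best$convergence == 0L, nodes = nodes, a0 = a0),
    class = "traffic_layout"
  )
}

#' @export
print.traffic_layout <- function(x, ...) {
  cat(sprintf("<traffic_layout> %d compartments, energy %.4f%s\n",
              nrow(x$positions), x$energy,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Spatial stacking metric of maturation chains
#'
#' Mean Euclidean distance between compartments connected by a maturation
#' edge, scaled by the mean (over compartments) nearest-neighbor
#' distance. A value near 1 means maturation partners sit at
#' nearest-neighbor spacing — maturation chains form spatial stacks, as
#' Golgi cisternae do.
#'
#' @param layout a `traffic_layout` (or a bare `n x 2` position matrix
#'   with `nodes` supplied via `net`).
#' @param net the `traffic_network` supplying the maturation edges.
#' @return scalar; `NA` if the network has no maturation edges between
#'   distinct compartments.
#' @export
stacking_metric <- function(layout, net) {
  pos <- if (inherits(layout, "traffic_layout")) layout$positions else layout
  nodes <- if (inherits(layout, "traffic_layout")) layout$nodes else net$nodes
  me <- net$maturation_edges
  me <- me[me$from != me$to, , drop = FALSE]
  if (!nrow(me)) return(NA_real_)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nn <- mean(apply(d, 1L, min))
  pairs <- cbind(match(me$from, nodes), match(me$to, nodes))
  mean(d[pairs]) / nn
}

#' Stacking metric of an identity-shuffled control
#'
#' Keeps the optimized positions fixed but randomly permutes which
#' compartment occupies which position, then recomputes the stacking
#' metric. This is the control against which the optimized layout's
#' stacking is judged.
#'
#' @param layout a `traffic_layout`.
#' @param net the corresponding `traffic_network`.
#' @param seed optional integer passed to `set.seed()`.
#' @return scalar stacking metric of the shuffled assignment.
#' @export
shuffled_stacking_metric <- function(layout, net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(nrow(layout$positions))
  shuffled <- layout
  shuffled$positions <- layout$positions[perm, , drop = FALSE]
  stacking_metric(shuffled, net)
}
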