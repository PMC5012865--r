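#' Budding/fusion rule sets
#'
#' The dynamics of the Boolean traffic model are fully specified by two
#' `C x V` binary matrices with `C = V = 2^N - 1`:
#'
#' * the budding matrix `G`: `G[i, j] = 1` means compartment type `i` buds
#'   vesicle type `j`. A vesicle can only carry labels present on its source
#'   compartment, so the support of `G` is restricted to bitwise subsets
#'   (the Sierpinski pattern), and each row has at most `A` non-zero
#'   entries, one per adaptor/coatomer complex.
#' * the fusion matrix `F`: `F[i, j] = 1` means vesicle type `j` fuses into
#'   compartment type `i` whenever that compartment is present. `F` is
#'   unconstrained.
#'
#' @param G,F binary `C x V` matrices (rows: compartment index, columns:
#'   vesicle index, both 1-based composition indices).
#' @param N number of molecular label types.
#' @param A number of adaptor/coatomer complexes (max distinct vesicles per
#'   compartment row of `G`).
#' @param g,f optional sampling propensities recorded for provenance.
#' @param seed optional RNG seed recorded for provenance.
#' @return an object of class `ruleset`.
#' @seealso [sample_rules()] for random generation, [run_to_orbit()] for the
#'   dynamics.
#' @export
ruleset <- function(G, F, N, A = NULL, g = NULL, f = NULL, seed = NULL) {
  N <- as.integer(N)
  C <- 2L^N - 1L
  G <- matrix(as.integer(G), C, C)
  F <- matrix(as.integer(F), C, C)
  rs <- structure(
    list(
      N = N, A = if (is.null(A)) NULL else as.integer(A),
      G = G, F = F, g = g, f = f, seed = seed,
      bits = composition_bits(N),
      weights = 2^((N - 1L):0L)
    ),
    class = "ruleset"
  )
  validate_ruleset(rs)
  rs
}

#' Validate the structural invariants of a rule set
#'
#' Checks binarity, the subset (Sierpinski) constraint on `G`, and the
#' per-row adaptor budget when `A` is recorded.
#'
#' @param rs a [ruleset()].
#' @return `rs`, invisibly; errors on violation.
#' @export
validate_ruleset <- function(rs) {
  C <- 2L^rs$N - 1L
  stopifnot(
    is.matrix(rs$G), is.matrix(rs$F),
    all(dim(rs$G) == c(C, C)), all(dim(rs$F) == c(C, C))
  )
  if (any(rs$G != 0L & rs$G != 1L) || any(rs$F != 0L & rs$F != 1L)) {
    stop("G and F must be binary matrices")
  }
  # subset constraint: G[i, j] = 1 requires v(j) a bitwise subset of c(i)
  bad <- which(rs$G == 1L, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[, 1L]; j <- bad[, 2L]
    if (any(bitwAnd(j, i) != j)) {
      stop("G violates the subset constraint: some vesicle is not a subset of its source")
    }
  }
  if (!is.null(rs$A) && any(rowSums(rs$G) > rs$A)) {
    stop("some row of G has more than A distinct vesicles")
  }
  invisible(rs)
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf(
    "<ruleset> N = %d labels, %d compartment/vesicle types; %d budding rules, %d fusion rules\n",
    x$N, 2L^x$N - 1L, sum(x$G), sum(x$F)
  ))
  if (!is.null(x$A)) cat(sprintf("  A = %d adaptors", x$A))
  if (!is.null(x$g)) cat(sprintf(", g = %g, f = %g", x$g, x$f))
  if (!is.null(x$seed)) cat(sprintf(", seed = %d", x$seed))
  cat("\n")
  invisible(x)
}

#' Sample a random budding/fusion rule set
#'
#' For every compartment type `i`, `A` candidate vesicles are drawn by
#' masking the compartment composition elementwise with independent
#' Bernoulli(`g`) variables (each adaptor loads each label carried by the
#' compartment with probability `g`). Duplicate candidates and the zero
#' vesicle are dropped, so rows of `G` carry between 0 and `A` ones. Every
#' entry of `F` is an independent Bernoulli(`f`) draw. Uses the current R
#' RNG stream; call `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param N number of molecular label types.
#' @param A number of adaptor/coatomer complexes.
#' @param g cargo-loading propensity in `[0, 1]`.
#' @param f fusion propensity in `[0, 1]`.
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#'   and the seed is recorded in the result.
#' @return a [ruleset()].
#' @examples
#' rs <- sample_rules(N = 4, A = 2, g = 0.5, f = 0.2, seed = 1)
#' rs
#' @export
sample_rules <- function(N, A, g, f, seed = NULL) {
  stopifnot(N >= 1, A >= 1, g >= 0, g <= 1, f >= 0, f <= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  C <- 2L^N - 1L
  bits <- composition_bits(N)
  w <- 2^((N - 1L):0L)
  G <- matrix(0L, C, C)
  for (i in seq_len(C)) {
    mask <- matrix(stats::rbinom(A * N, 1L, g), nrow = A, ncol = N)
    cand <- mask * rep(bits[i, ], each = A)
    idx <- as.integer(cand %*% w)
    idx <- unique(idx[idx > 0L])
    if (length(idx)) G[i, idx] <- 1L
  }
  F <- matrix(stats::rbinom(C * C, 1L, f), C, C)
  ruleset(G, F, N = N, A = A, g = g, f = f, seed = seed)
}

#' Sample a random initial cell state
#'
#' The number of initial compartments is uniform on `{1, ..., 2N - 1}`
#' (linear in the label count, so initial conditions stay comparable in
#' size as `N` grows); each compartment index is then drawn uniformly from
#' the `2^N - 1` non-zero compositions. Duplicates collapse under set
#' semantics, so the returned state can be smaller than the drawn count.
#'
#' @param N number of molecular label types.
#' @param seed optional integer passed to `set.seed()`.
#' @return a sorted, duplicate-free integer vector of composition indices.
#' @export
sample_initial_state <- function(N, seed = NULL) {
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  C <- 2L^N - 1L
  count <- sample.int(2L * N - 1L, 1L)
  sort(unique(sample.int(C, count, replace = TRUE)))
}

#' Assert that a vector is a valid cell state
#' @keywords internal
#' @noRd
as_cell_state <- function(state, N) {
  state <- as.integer(state)
  C <- 2L^as.integer(N) - 1L
  if (any(is.na(state) | state < 1L | state > C)) {
    stop("cell state indices must lie in [1, 2^N - 1]")
  }
  s <- sort(unique(state))
  s
}
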