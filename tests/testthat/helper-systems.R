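# Hand-built reference systems used across test files.

# Two-label maturation chain: compartment [10] (index 2) buds its own X
# vesicle [10]; compartment [01] (index 1) buds Y vesicles [01]; Y
# vesicles fuse to [10]; X vesicles are orphans and nucleate new [10]
# compartments homotypically. The state {[01], [10]} = {1, 2} is a fixed
# point: [10] matures to [01], [01] vesiculates, the orphan X vesicle
# recreates [10].
chain_ruleset_n2 <- function() {
  G <- matrix(0L, 3, 3)
  G[2, 2] <- 1L # [10] buds [10]
  G[1, 1] <- 1L # [01] buds [01]
  F <- matrix(0L, 3, 3)
  F[2, 1] <- 1L # vesicle [01] fuses into compartment [10]
  ruleset(G, F, N = 2)
}

# Transport-balanced single compartment (N = 1): buds and refuses its own
# vesicle, composition unchanged.
balanced_ruleset_n1 <- function() {
  G <- matrix(1L, 1, 1)
  F <- matrix(1L, 1, 1)
  ruleset(G, F, N = 1)
}

# Straight-line evaluation of one synchronous update, written without the
# vectorized matrix machinery: the independent oracle for the dynamics.
naive_step <- function(state, rules) {
  N <- rules$N
  C <- 2L^N - 1L
  jt <- integer(0)
  for (j in seq_len(C)) {
    for (i in state) if (rules$G[i, j] == 1L) jt <- union(jt, j)
  }
  jt <- sort(jt)
  new_state <- integer(0)
  for (j in jt) {
    fused <- FALSE
    for (i in state) if (rules$F[i, j] == 1L) fused <- TRUE
    if (!fused) new_state <- c(new_state, j) # orphan nucleates
  }
  for (i in state) {
    inb <- rep(0L, N); outb <- rep(0L, N)
    for (j in jt) {
      if (rules$G[i, j] == 1L) outb <- pmax(outb, index_to_bits(j, N))
      if (rules$F[i, j] == 1L) inb <- pmax(inb, index_to_bits(j, N))
    }
    cb <- index_to_bits(i, N)
    nb <- ifelse(inb == 1L, 1L, ifelse(outb == 1L, 0L, cb))
    idx <- bits_to_index(nb)
    if (idx > 0L) new_state <- c(new_state, idx)
  }
  sort(unique(new_state))
}

# Orbit detection by explicit trajectory traversal over naive_step.
naive_orbit <- function(rules, initial, max_steps = 1024L) {
  state <- sort(unique(as.integer(initial)))
  seen <- list()
  key <- function(s) if (length(s)) paste(s, collapse = ".") else "empty"
  seen[[key(state)]] <- 0L
  history <- list(state)
  for (t in seq_len(max_steps)) {
    state <- naive_step(state, rules)
    k <- key(state)
    if (!is.null(seen[[k]])) {
      first <- seen[[k]]
      return(list(reached = TRUE, period = t - first,
                  states = history[(first + 1L):t][seq_len(t - first)],
                  steps_to_orbit = first))
    }
    seen[[k]] <- t
    history[[t + 1L]] <- state
  }
  list(reached = FALSE, period = NA_integer_, states = NULL,
       steps_to_orbit = max_steps)
}

# A bare network object (nodes + typed edges) for graph-level tests that
# do not need Boolean provenance.
make_net <- function(nodes, creation = NULL, maturation = NULL,
                     vesicle = NULL, N = 7L, node_next = nodes) {
  empty <- data.frame(from = integer(0), to = integer(0))
  ves <- if (is.null(vesicle)) empty else vesicle
  ves$vesicles <- replicate(nrow(ves), integer(0), simplify = FALSE)
  structure(
    list(
      N = N, nodes = nodes, node_next = node_next,
      vesicle_edges = ves,
      creation_edges = if (is.null(creation)) empty else creation,
      maturation_edges = if (is.null(maturation)) empty else maturation,
      vesicle_types = integer(0), homotypic_types = integer(0)
    ),
    class = "traffic_network"
  )
}

# Matrix-permutation canonicalizer: the independent oracle for motif
# canonicalization (decodes to adjacency matrices, permutes rows/columns,
# re-encodes).
perm_canonical <- function(code) {
  decode <- function(code, type) {
    m <- matrix(FALSE, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      bit <- (type - 1L) * 9L + (a - 1L) * 3L + b
      m[a, b] <- bitwAnd(bitwShiftR(code, bit - 1L), 1L) == 1L
    }
    m
  }
  cre <- decode(code, 1L); mat <- decode(code, 2L)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- Inf
  for (p in perms) {
    inv <- order(p)
    cand <- encode_motif(cre[inv, inv], mat[inv, inv])
    best <- min(best, cand)
  }
  as.integer(best)
}
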