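#' Vesicles budded by a cell state
#'
#' Returns the sorted set `Jt` of vesicle types generated at one timepoint:
#' the union, over all present compartments, of the non-zero columns of
#' their budding rows.
#'
#' @param state sorted integer vector of compartment composition indices.
#' @param rules a [ruleset()].
#' @return sorted integer vector of vesicle indices.
#' @export
budded_vesicles <- function(state, rules) {
  state <- as_cell_state(state, rules$N)
  if (length(state) == 0L) return(integer(0))
  which(colSums(rules$G[state, , drop = FALSE]) > 0L)
}

#' Outgoing and incoming vesicle flows of one compartment
#'
#' For a compartment `i` present in `state`, the outgoing set is
#' `{j in Jt : G[i, j] = 1}` and the incoming set is
#' `{j in Jt : F[i, j] = 1}` — fusion only draws on vesicles actually
#' budded somewhere at this timepoint, so orphan vesicles (budded but with
#' no fusion target anywhere) are possible.
#'
#' @param i compartment composition index, must be a member of `state`.
#' @param state sorted integer vector of compartment indices.
#' @param rules a [ruleset()].
#' @return list with sorted integer vectors `outgoing` and `incoming`.
#' @export
vesicle_flows <- function(i, state, rules) {
  state <- as_cell_state(state, rules$N)
  i <- as.integer(i)
  if (!(i %in% state)) stop("compartment ", i, " is not present in the state")
  jt <- budded_vesicles(state, rules)
  list(
    outgoing = jt[rules$G[i, jt] == 1L],
    incoming = jt[rules$F[i, jt] == 1L]
  )
}

#' Bitwise OR collapse of a set of vesicle compositions
#'
#' Collapses a set of vesicle types into the single binary vector whose
#' entry `n` is 1 iff any vesicle in the set carries label `n`. The empty
#' set collapses to the zero vector.
#'
#' @param vesicles integer vector of vesicle composition indices.
#' @param N number of molecular label types.
#' @return integer 0/1 vector of length `N`.
#' @export
collapse_or <- function(vesicles, N) {
  vesicles <- as.integer(vesicles)
  idx <- Reduce(bitwOr, vesicles, accumulate = FALSE, right = FALSE, init = 0L)
  index_to_bits(idx, N)
}

#' One Boolean composition update
#'
#' Binary mass balance for a single compartment: per label `n`, the updated
#' value is `in_n OR (NOT out_n AND c_n)` — a label is gained if it fuses in
#' and does not bud out, lost if it buds out and does not fuse in, and
#' retained otherwise. The result may be the zero composition, in which
#' case the compartment has vesiculated.
#'
#' @param c_bits,incoming,outgoing integer 0/1 vectors of equal length: the
#'   current composition and the collapsed incoming/outgoing vesicle
#'   vectors.
#' @return integer 0/1 vector, the updated composition.
#' @export
update_compartment <- function(c_bits, incoming, outgoing) {
  stopifnot(length(c_bits) == length(incoming), length(c_bits) == length(outgoing))
  as.integer(incoming | (!outgoing & c_bits))
}

#' Orphan vesicles of a cell state
#'
#' The subset of budded vesicles `Jt` whose fusion column is zero on every
#' present compartment: such vesicles find no target this timepoint. Under
#' the homeostasis-search protocol they are granted homotypic fusion and
#' nucleate new compartments of their own composition.
#'
#' @inheritParams budded_vesicles
#' @return sorted integer vector of vesicle indices.
#' @export
find_orphans <- function(state, rules) {
  state <- as_cell_state(state, rules$N)
  jt <- budded_vesicles(state, rules)
  if (length(jt) == 0L) return(integer(0))
  jt[colSums(rules$F[state, jt, drop = FALSE]) == 0L]
}

#' One synchronous update of the whole cell
#'
#' Applies the Boolean update to every present compartment and nucleates
#' one new compartment per orphan vesicle type. The next state is the union
#' of created compartments and updated compartments, with the zero
#' composition excluded, duplicates removed, and indices sorted.
#' Bookkeeping outputs record creations, maturations (composition changed
#' to a non-zero value), and dissipations (updated to zero).
#'
#' @inheritParams budded_vesicles
#' @return list with elements:
#'   * `state`: the next cell state (sorted integer vector),
#'   * `created`: orphan vesicle indices nucleating new compartments,
#'   * `matured`: two-column integer matrix `(from, to)` of composition
#'     changes,
#'   * `dissipated`: indices of compartments that vesiculated,
#'   * `updated`: integer vector, the raw per-compartment updates aligned
#'     with the input state (0 = vesiculated).
#' @export
step_cell <- function(state, rules) {
  state <- as_cell_state(state, rules$N)
  N <- rules$N
  if (length(state) == 0L) {
    return(list(
      state = integer(0), created = integer(0),
      matured = matrix(integer(0), 0, 2, dimnames = list(NULL, c("from", "to"))),
      dissipated = integer(0), updated = integer(0)
    ))
  }
  Gs <- rules$G[state, , drop = FALSE]
  jt <- which(colSums(Gs) > 0L)
  if (length(jt)) {
    Fsj <- rules$F[state, jt, drop = FALSE]
    orphans <- jt[colSums(Fsj) == 0L]
    in_bits <- (Fsj %*% rules$bits[jt, , drop = FALSE]) > 0
  } else {
    orphans <- integer(0)
    in_bits <- matrix(FALSE, length(state), N)
  }
  out_bits <- (Gs %*% rules$bits) > 0
  cur_bits <- rules$bits[state, , drop = FALSE] > 0
  new_bits <- in_bits | (!out_bits & cur_bits)
  updated <- as.integer(new_bits %*% rules$weights)
  changed <- updated != state & updated != 0L
  list(
    state = sort(unique(c(orphans, updated[updated > 0L]))),
    created = orphans,
    matured = cbind(from = state[changed], to = updated[changed]),
    dissipated = state[updated == 0L],
    updated = updated
  )
}

#' Iterate the Boolean dynamics until a periodic orbit
#'
#' Runs synchronous updates from an initial state, hashing every visited
#' state; the first revisited state defines the orbit and its period. A
#' period-1 orbit is a homeostatic state: the set of compartment types
#' repeats exactly even as individual compartments interconvert. The orbit
#' records which orphan vesicle types are being nucleated by homotypic
#' fusion within the orbit (for a homeostatic state, the orphans of the
#' fixed point).
#'
#' @param rules a [ruleset()].
#' @param initial integer vector of initial compartment indices.
#' @param max_steps cap on the number of updates (default 1024).
#' @return an object of class `orbit`: list with `states` (list of cell
#'   states forming one period), `period`, `steps_to_orbit` (updates before
#'   entering the orbit), `reached` (logical; `FALSE` if no repeat within
#'   `max_steps`, in which case `states` holds the last state visited),
#'   `homotypic_types` (vesicle indices nucleating within the orbit) and
#'   `degenerate` (`TRUE` for the empty period-1 state).
#' @examples
#' rs <- sample_rules(N = 4, A = 2, g = 0.4, f = 0.4, seed = 7)
#' orb <- run_to_orbit(rs, sample_initial_state(4, seed = 7))
#' orb$period
#' @export
run_to_orbit <- function(rules, initial, max_steps = 1024L) {
  state <- as_cell_state(initial, rules$N)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  state_key <- function(s) if (length(s)) paste(s, collapse = ".") else "empty"
  assign(state_key(state), 0L, envir = seen)
  history <- vector("list", max_steps + 1L)
  history[[1L]] <- state
  first <- NA_integer_
  steps <- NA_integer_
  for (t in seq_len(max_steps)) {
    state <- step_cell(state, rules)$state
    k <- state_key(state)
    prev <- seen[[k]]
    if (!is.null(prev)) {
      first <- prev
      steps <- t
      break
    }
    assign(k, t, envir = seen)
    history[[t + 1L]] <- state
  }
  if (is.na(first)) {
    return(structure(
      list(
        states = list(state), period = NA_integer_,
        steps_to_orbit = max_steps, reached = FALSE,
        homotypic_types = integer(0), degenerate = FALSE,
        rules_N = rules$N
      ),
      class = "orbit"
    ))
  }
  period <- steps - first
  states <- history[(first + 1L):(first + period)]
  homotypic <- sort(unique(unlist(lapply(states, find_orphans, rules = rules))))
  structure(
    list(
      states = states, period = period, steps_to_orbit = first,
      reached = TRUE, homotypic_types = as.integer(homotypic),
      degenerate = period == 1L && length(states[[1L]]) == 0L,
      rules_N = rules$N
    ),
    class = "orbit"
  )
}

#' @export
print.orbit <- function(x, ...) {
  if (!x$reached) {
    cat("<orbit> no periodic orbit within step cap\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<orbit> period %d after %d steps; %d compartment(s); %d homotypic vesicle type(s)%s\n",
    x$period, x$steps_to_orbit, length(x$states[[1L]]),
    length(x$homotypic_types),
    if (x$degenerate) " [degenerate empty state]" else ""
  ))
  invisible(x)
}

#' Is an orbit a homeostatic state?
#'
#' A homeostatic state is a non-degenerate period-1 orbit: the same
#' non-empty set of compartment types is reproduced by every update.
#'
#' @param orbit an object returned by [run_to_orbit()].
#' @return logical.
#' @export
is_homeostatic <- function(orbit) {
  isTRUE(orbit$reached) && orbit$period == 1L && !orbit$degenerate
}
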