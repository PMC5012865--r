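#' Build the typed traffic graph of a homeostatic state
#'
#' Nodes are the compartments of a period-1 state. Three directed edge sets
#' are derived from one evaluation of the update on that state:
#'
#' * vesicle edges `i1 -> i2` wherever some budded vesicle `j` satisfies
#'   `G[i1, j] = 1` and `F[i2, j] = 1` (the `G F'` coupling restricted to
#'   the state); the vesicle compositions carried are recorded per edge;
#' * creation edges `source -> created` for every orphan vesicle, linking
#'   the budding compartment to the compartment nucleated by homotypic
#'   fusion of that vesicle type (recorded to the existing node of that
#'   composition);
#' * maturation edges `old -> new` for compartments whose composition
#'   changes to a non-zero value (transport-balanced compartments have
#'   none; a node has at most one outgoing maturation edge since the
#'   update is deterministic).
#'
#' @param rules a [ruleset()].
#' @param orbit a homeostatic orbit from [run_to_orbit()], or a cell state
#'   (integer vector) that is a fixed point of the dynamics.
#' @return an object of class `traffic_network`: list with `N`, `nodes`,
#'   `node_next` (per-node updated composition; 0 = dissipates, equal =
#'   transport balance), `vesicle_edges` (data.frame `from`, `to`,
#'   `vesicles` list-column), `creation_edges` (data.frame `from`, `to`;
#'   `to` is also the carried vesicle composition), `maturation_edges`
#'   (data.frame `from`, `to`), `vesicle_types` (the budded set `Jt`) and
#'   `homotypic_types`.
#' @export
build_network <- function(rules, orbit) {
  if (inherits(orbit, "orbit")) {
    if (!is_homeostatic(orbit)) {
      stop("build_network requires a homeostatic (non-degenerate period-1) orbit")
    }
    state <- orbit$states[[1L]]
  } else {
    state <- as_cell_state(orbit, rules$N)
  }
  step <- step_cell(state, rules)
  if (!identical(step$state, state)) {
    stop("state is not a fixed point of the dynamics")
  }
  jt <- budded_vesicles(state, rules)
  orphans <- step$created

  # vesicle edges: accumulate vesicle compositions per ordered (from, to)
  ves_from <- integer(0); ves_to <- integer(0); ves_j <- integer(0)
  for (j in jt) {
    src <- state[rules$G[state, j] == 1L]
    tgt <- state[rules$F[state, j] == 1L]
    if (length(src) && length(tgt)) {
      pairs <- expand.grid(from = src, to = tgt, KEEP.OUT.ATTRS = FALSE)
      ves_from <- c(ves_from, pairs$from)
      ves_to <- c(ves_to, pairs$to)
      ves_j <- c(ves_j, rep(j, nrow(pairs)))
    }
  }
  if (length(ves_from)) {
    key <- paste(ves_from, ves_to)
    uniq <- !duplicated(key)
    vesicle_edges <- data.frame(from = ves_from[uniq], to = ves_to[uniq])
    vesicle_edges$vesicles <- lapply(key[uniq], function(k) sort(ves_j[key == k]))
    o <- order(vesicle_edges$from, vesicle_edges$to)
    vesicle_edges <- vesicle_edges[o, , drop = FALSE]
    rownames(vesicle_edges) <- NULL
  } else {
    vesicle_edges <- data.frame(from = integer(0), to = integer(0))
    vesicle_edges$vesicles <- list()
  }

  # creation edges: orphan j budded by source i nucleates compartment j
  cre_from <- integer(0); cre_to <- integer(0)
  for (j in orphans) {
    src <- state[rules$G[state, j] == 1L]
    cre_from <- c(cre_from, src)
    cre_to <- c(cre_to, rep(j, length(src)))
  }
  creation_edges <- data.frame(from = cre_from, to = cre_to)
  if (nrow(creation_edges)) {
    creation_edges <- creation_edges[order(creation_edges$from, creation_edges$to), , drop = FALSE]
    rownames(creation_edges) <- NULL
  }

  mat <- step$matured
  maturation_edges <- data.frame(from = as.integer(mat[, "from"]),
                                 to = as.integer(mat[, "to"]))

  structure(
    list(
      N = rules$N, nodes = state, node_next = step$updated,
      vesicle_edges = vesicle_edges, creation_edges = creation_edges,
      maturation_edges = maturation_edges,
      vesicle_types = jt, homotypic_types = orphans
    ),
    class = "traffic_network"
  )
}

#' @export
print.traffic_network <- function(x, ...) {
  cat(sprintf(
    "<traffic_network> N = %d; %d compartments, %d vesicle types; edges: %d vesicle, %d creation, %d maturation\n",
    x$N, length(x$nodes), length(x$vesicle_types),
    nrow(x$vesicle_edges), nrow(x$creation_edges), nrow(x$maturation_edges)
  ))
  invisible(x)
}

#' All typed edges of a network as one data.frame
#' @param net a `traffic_network`.
#' @param types which edge types to include.
#' @return data.frame with columns `from`, `to`, `type`.
#' @export
network_edges <- function(net, types = c("vesicle", "creation", "maturation")) {
  out <- list()
  if ("vesicle" %in% types && nrow(net$vesicle_edges)) {
    out$v <- data.frame(from = net$vesicle_edges$from,
                        to = net$vesicle_edges$to, type = "vesicle")
  }
  if ("creation" %in% types && nrow(net$creation_edges)) {
    out$c <- data.frame(from = net$creation_edges$from,
                        to = net$creation_edges$to, type = "creation")
  }
  if ("maturation" %in% types && nrow(net$maturation_edges)) {
    out$m <- data.frame(from = net$maturation_edges$from,
                        to = net$maturation_edges$to, type = "maturation")
  }
  if (!length(out)) {
    return(data.frame(from = integer(0), to = integer(0), type = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weakly connected subsets of a traffic network
#'
#' Partitions the compartments into subsets connected within themselves
#' (over the union of all three edge types) but mutually disconnected from
#' one another.
#'
#' @param net a `traffic_network`.
#' @return list of sorted integer vectors, one per subset.
#' @export
connected_subsets <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "weak")
  split(net$nodes, comp$membership)
}

#' Is a network trivial?
#'
#' A trivial homeostatic state is one in which no compartment connects to
#' any other: there is no edge of any type between two distinct nodes.
#'
#' @param net a `traffic_network`.
#' @return logical.
#' @export
is_trivial <- function(net) {
  e <- network_edges(net)
  !any(e$from != e$to)
}

#' Maturation chains and cycles of a network
#'
#' A maturation chain starts at a compartment with an incoming creation
#' edge and proceeds along maturation edges until a compartment with no
#' outgoing maturation edge (terminal kind `"fixed"`). If a compartment
#' already on the chain repeats, the chain is truncated before the repeat
#' and the cycle is stored separately (terminal kind `"cycle"`). A fixed
#' terminal `dissipates` if its next update is the zero composition.
#'
#' @param net a `traffic_network`.
#' @return list with
#'   * `chains`: data.frame with columns `start`, `length` (number of
#'     maturation edges traversed), `terminal`, `terminal_kind`
#'     (`"fixed"`/`"cycle"`), `dissipates` (NA for cycle terminals) and a
#'     `path` list-column of node sequences;
#'   * `cycles`: list of integer vectors, the distinct maturation cycles
#'     encountered (also reported when fed by no chain).
#' @export
find_chains <- function(net) {
  nodes <- net$nodes
  mat_next <- rep(NA_integer_, length(nodes))
  names(mat_next) <- as.character(nodes)
  if (nrow(net$maturation_edges)) {
    mat_next[as.character(net$maturation_edges$from)] <- net$maturation_edges$to
  }
  node_next <- net$node_next
  names(node_next) <- as.character(nodes)

  starts <- sort(unique(net$creation_edges$to))
  chains <- list()
  cycles <- list()
  for (s in starts) {
    path <- s
    repeat {
      nxt <- mat_next[[as.character(path[length(path)])]]
      if (is.na(nxt)) {
        chains[[length(chains) + 1L]] <- list(
          start = s, path = path, length = length(path) - 1L,
          terminal = path[length(path)], terminal_kind = "fixed",
          dissipates = node_next[[as.character(path[length(path)])]] == 0L
        )
        break
      }
      hit <- match(nxt, path)
      if (!is.na(hit)) {
        cyc <- path[hit:length(path)]
        cycles[[length(cycles) + 1L]] <- cyc
        chains[[length(chains) + 1L]] <- list(
          start = s, path = path[seq_len(hit - 1L)], length = hit - 1L,
          terminal = if (hit > 1L) path[hit - 1L] else s,
          terminal_kind = "cycle", dissipates = NA
        )
        break
      }
      path <- c(path, nxt)
    }
  }
  # maturation cycles not fed by any creation edge (pure oscillators)
  cycle_key <- function(cy) paste(sort(cy), collapse = ".")
  seen_cycles <- vapply(cycles, cycle_key, character(1))
  visited <- rep(FALSE, length(nodes))
  for (k in seq_along(nodes)) {
    if (visited[k]) next
    path <- nodes[k]
    repeat {
      visited[match(path[length(path)], nodes)] <- TRUE
      nxt <- mat_next[[as.character(path[length(path)])]]
      if (is.na(nxt)) break
      hit <- match(nxt, path)
      if (!is.na(hit)) {
        cyc <- path[hit:length(path)]
        if (!cycle_key(cyc) %in% seen_cycles) {
          cycles[[length(cycles) + 1L]] <- cyc
          seen_cycles <- c(seen_cycles, cycle_key(cyc))
        }
        break
      }
      if (visited[match(nxt, nodes)]) break
      path <- c(path, nxt)
    }
  }
  if (length(chains)) {
    chain_df <- data.frame(
      start = vapply(chains, `[[`, integer(1), "start"),
      length = vapply(chains, `[[`, integer(1), "length"),
      terminal = vapply(chains, `[[`, integer(1), "terminal"),
      terminal_kind = vapply(chains, `[[`, character(1), "terminal_kind"),
      dissipates = vapply(chains, function(ch) as.logical(ch$dissipates), logical(1))
    )
    chain_df$path <- lapply(chains, `[[`, "path")
  } else {
    chain_df <- data.frame(
      start = integer(0), length = integer(0), terminal = integer(0),
      terminal_kind = character(0), dissipates = logical(0)
    )
    chain_df$path <- list()
  }
  # deduplicate cycles by node set
  if (length(cycles)) {
    cycles <- cycles[!duplicated(vapply(cycles, cycle_key, character(1)))]
  }
  list(chains = chain_df, cycles = cycles)
}

#' Retrograde-vesicle statistics of a network
#'
#' Over ordered pairs of distinct compartments `(A, B)`, computes the
#' fraction carrying a vesicle edge from `B` back to `A`, both overall
#' (`f_all`) and conditioned on three pair subsets: `A` sends a vesicle to
#' `B` (`f_vesicle_pairs`), `B` matures to `A` (`f_B_matures_to_A`), and
#' `A` matures to `B` (`f_A_matures_to_B`). In a cisternal maturation
#' chain the last conditional is the retrograde fraction: the younger
#' compartment `A` receiving a vesicle from the older successor `B` it
#' matures into. Vesicle self-edges are excluded from all pair counts.
#'
#' @param net a `traffic_network`.
#' @return list with the four fractions (`NA` when the conditioning subset
#'   is empty), plus `n_pairs` and `n_maturation_edges`.
#' @export
retrograde_stats <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  if (n < 2L) {
    return(list(f_all = NA_real_, f_vesicle_pairs = NA_real_,
                f_B_matures_to_A = NA_real_, f_A_matures_to_B = NA_real_,
                n_pairs = 0L, n_maturation_edges = nrow(net$maturation_edges)))
  }
  idx <- function(v) match(v, nodes)
  ves <- matrix(FALSE, n, n)
  if (nrow(net$vesicle_edges)) {
    ves[cbind(idx(net$vesicle_edges$from), idx(net$vesicle_edges$to))] <- TRUE
  }
  mat <- matrix(FALSE, n, n)
  if (nrow(net$maturation_edges)) {
    mat[cbind(idx(net$maturation_edges$from), idx(net$maturation_edges$to))] <- TRUE
  }
  pairs <- which(outer(seq_len(n), seq_len(n), "!="), arr.ind = TRUE)
  a <- pairs[, 1L]; b <- pairs[, 2L]
  has_ba <- ves[cbind(b, a)]
  cond_mean <- function(mask) if (any(mask)) mean(has_ba[mask]) else NA_real_
  list(
    f_all = mean(has_ba),
    f_vesicle_pairs = cond_mean(ves[cbind(a, b)]),
    f_B_matures_to_A = cond_mean(mat[cbind(b, a)]),
    f_A_matures_to_B = cond_mean(mat[cbind(a, b)]),
    n_pairs = nrow(pairs),
    n_maturation_edges = nrow(net$maturation_edges)
  )
}

#' Molecular labels with sinks
#'
#' For each label, builds the directed flow graph whose edges are the
#' vesicle edges carrying that label plus the creation edges whose orphan
#' vesicle carries it. The label has a sink if this flow graph contains a
#' terminal strongly connected component (no flow edge leaving it) that
#' receives at least one flow edge from outside: the label is delivered to
#' a compartment group and never exported, implying a need for
#' compensatory synthesis. The flow-graph predicate is exposed via
#' `flow_edges` so alternative conventions can be swapped in.
#'
#' @param net a `traffic_network`.
#' @param flow_edges optional function `(net, label_bit)` returning a
#'   data.frame `from`, `to` of flow edges for one label; defaults to the
#'   vesicle + creation convention above.
#' @return integer vector of label indices (1 = most significant bit) that
#'   have a sink.
#' @export
label_sinks <- function(net, flow_edges = NULL) {
  if (is.null(flow_edges)) flow_edges <- default_flow_edges
  sinks <- integer(0)
  for (b in seq_len(net$N)) {
    e <- flow_edges(net, b)
    if (!nrow(e)) next
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$from), to = as.character(e$to)),
      directed = TRUE,
      vertices = data.frame(name = as.character(net$nodes))
    )
    sc <- igraph::components(g, mode = "strong")
    cg <- igraph::contract(g, sc$membership)
    cg <- igraph::simplify(cg, remove.loops = TRUE)
    outdeg <- igraph::degree(cg, mode = "out")
    indeg <- igraph::degree(cg, mode = "in")
    if (any(outdeg == 0 & indeg > 0)) sinks <- c(sinks, b)
  }
  sinks
}

# default sink flow predicate: label is moved by vesicles (and by the
# orphan vesicles behind creation edges); the label bit b is the b-th most
# significant of N
default_flow_edges <- function(net, b) {
  shift <- net$N - b
  carries <- function(j) bitwAnd(bitwShiftR(as.integer(j), shift), 1L) == 1L
  from <- integer(0); to <- integer(0)
  if (nrow(net$vesicle_edges)) {
    keep <- vapply(net$vesicle_edges$vesicles, function(js) any(carries(js)), logical(1))
    from <- c(from, net$vesicle_edges$from[keep])
    to <- c(to, net$vesicle_edges$to[keep])
  }
  if (nrow(net$creation_edges)) {
    keep <- carries(net$creation_edges$to)
    from <- c(from, net$creation_edges$from[keep])
    to <- c(to, net$creation_edges$to[keep])
  }
  data.frame(from = from, to = to)
}

#' Per-network summary statistics
#'
#' One row per network: compartment and vesicle-type counts, stable
#' compartments (transport balance, no outgoing maturation edge and a
#' non-zero self-reproducing update), maturation and homotypic-creation
#' fractions, connected subsets, chain counts and lengths, cycle presence,
#' labels per compartment/vesicle, and sink counts.
#'
#' @param networks a list of `traffic_network` objects or a
#'   `traffic_sweep`.
#' @return data.frame with one row per network; chain lengths are attached
#'   as a list-column `chain_lengths`.
#' @export
summarize_networks <- function(networks) {
  if (inherits(networks, "traffic_sweep")) networks <- networks$networks
  rows <- lapply(seq_along(networks), function(k) {
    net <- networks[[k]]
    n <- length(net$nodes)
    ch <- find_chains(net)
    maturing <- unique(net$maturation_edges$from)
    created <- unique(net$creation_edges$to)
    stable <- sum(net$node_next == net$nodes)
    data.frame(
      network = if (!is.null(names(networks))) names(networks)[k] else as.character(k),
      n_compartments = n,
      n_vesicle_types = length(net$vesicle_types),
      n_stable = stable,
      maturation_fraction = length(maturing) / n,
      creation_fraction = length(created) / n,
      n_subsets = length(connected_subsets(net)),
      trivial = is_trivial(net),
      n_chains = nrow(ch$chains),
      n_chains_maturing = sum(ch$chains$length >= 1L |
                                ch$chains$terminal_kind == "cycle"),
      has_cycle = length(ch$cycles) > 0L,
      n_homotypic = length(net$homotypic_types),
      mean_labels_compartment = mean(popcount(net$nodes, net$N)),
      mean_labels_vesicle = if (length(net$vesicle_types)) {
        mean(popcount(net$vesicle_types, net$N))
      } else NA_real_,
      n_sinks = length(label_sinks(net))
    )
  })
  out <- do.call(rbind, rows)
  out$chain_lengths <- lapply(networks, function(net) find_chains(net)$chains$length)
  rownames(out) <- NULL
  out
}
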