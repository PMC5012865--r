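#' Convert a traffic network to an igraph object
#'
#' Edges carry a `type` attribute (`"vesicle"`, `"creation"`,
#' `"maturation"`); vesicle edges additionally carry the compositions
#' transported, comma-collapsed into the `vesicles` attribute. Vertex
#' names are the composition indices; the `bits` attribute holds the
#' readable bit strings.
#'
#' @param net a `traffic_network`.
#' @param types edge types to include.
#' @return an igraph directed graph.
#' @export
as_igraph <- function(net, types = c("vesicle", "creation", "maturation")) {
  e <- network_edges(net, types)
  vesicles <- rep(NA_character_, nrow(e))
  if ("vesicle" %in% types && nrow(net$vesicle_edges)) {
    vesicles[e$type == "vesicle"] <-
      vapply(net$vesicle_edges$vesicles, paste, character(1), collapse = ",")
  }
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to),
               type = e$type, vesicles = vesicles),
    directed = TRUE,
    vertices = data.frame(name = as.character(net$nodes),
                          bits = format_composition(net$nodes, net$N))
  )
}

#' Serialize a rule set to JSON
#'
#' The JSON form is canonical and lossless: a header with `N`, `A`, `g`,
#' `f` and `seed`, plus sparse triplet lists (`i`, `j`) of the non-zero
#' entries of `G` and `F`.
#'
#' @param rules a [ruleset()].
#' @param path file path; `.json` recommended.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rules, path) {
  trip <- function(M) {
    nz <- which(M == 1L, arr.ind = TRUE)
    list(i = as.integer(nz[, 1L]), j = as.integer(nz[, 2L]))
  }
  obj <- list(
    N = rules$N, A = rules$A, g = rules$g, f = rules$f, seed = rules$seed,
    G = trip(rules$G), F = trip(rules$F)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @param path path of a JSON file written by [write_ruleset()].
#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- 2L^obj$N - 1L
  fill <- function(tr) {
    M <- matrix(0L, C, C)
    if (length(tr$i)) M[cbind(as.integer(tr$i), as.integer(tr$j))] <- 1L
    M
  }
  ruleset(fill(obj$G), fill(obj$F), N = obj$N, A = obj$A,
          g = obj$g, f = obj$f, seed = obj$seed)
}

#' Serialize a rule set as a pair of MatrixMarket files
#'
#' Writes `<prefix>_G.mtx`, `<prefix>_F.mtx` (sparse MatrixMarket) and
#' `<prefix>_meta.json` (the `N`, `A`, `g`, `f`, `seed` header).
#'
#' @param rules a [ruleset()].
#' @param prefix path prefix for the three files.
#' @return character vector of the three paths, invisibly.
#' @export
write_ruleset_mtx <- function(rules, prefix) {
  pg <- paste0(prefix, "_G.mtx")
  pf <- paste0(prefix, "_F.mtx")
  pm <- paste0(prefix, "_meta.json")
  Matrix::writeMM(Matrix::Matrix(rules$G + 0, sparse = TRUE), pg)
  Matrix::writeMM(Matrix::Matrix(rules$F + 0, sparse = TRUE), pf)
  jsonlite::write_json(
    list(N = rules$N, A = rules$A, g = rules$g, f = rules$f, seed = rules$seed),
    pm, auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(c(pg, pf, pm))
}

#' @rdname write_ruleset_mtx
#' @export
read_ruleset_mtx <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  G <- as.matrix(Matrix::readMM(paste0(prefix, "_G.mtx")))
  F <- as.matrix(Matrix::readMM(paste0(prefix, "_F.mtx")))
  ruleset(G, F, N = meta$N, A = meta$A, g = meta$g, f = meta$f, seed = meta$seed)
}

#' Serialize a traffic network to JSON (canonical, lossless)
#'
#' @param net a `traffic_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  obj <- list(
    N = net$N, nodes = net$nodes, node_next = net$node_next,
    vesicle_edges = list(from = net$vesicle_edges$from,
                         to = net$vesicle_edges$to,
                         vesicles = net$vesicle_edges$vesicles),
    creation_edges = list(from = net$creation_edges$from,
                          to = net$creation_edges$to),
    maturation_edges = list(from = net$maturation_edges$from,
                            to = net$maturation_edges$to),
    vesicle_types = net$vesicle_types,
    homotypic_types = net$homotypic_types
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ves <- data.frame(from = as.integer(obj$vesicle_edges$from %||% integer(0)),
                    to = as.integer(obj$vesicle_edges$to %||% integer(0)))
  vlist <- obj$vesicle_edges$vesicles
  ves$vesicles <- if (is.null(vlist)) {
    list()
  } else if (is.matrix(vlist)) {
    lapply(seq_len(nrow(vlist)), function(i) as.integer(vlist[i, ]))
  } else {
    lapply(vlist, as.integer)
  }
  structure(
    list(
      N = as.integer(obj$N), nodes = as.integer(obj$nodes),
      node_next = as.integer(obj$node_next),
      vesicle_edges = ves,
      creation_edges = data.frame(
        from = as.integer(obj$creation_edges$from %||% integer(0)),
        to = as.integer(obj$creation_edges$to %||% integer(0))),
      maturation_edges = data.frame(
        from = as.integer(obj$maturation_edges$from %||% integer(0)),
        to = as.integer(obj$maturation_edges$to %||% integer(0))),
      vesicle_types = as.integer(obj$vesicle_types),
      homotypic_types = as.integer(obj$homotypic_types)
    ),
    class = "traffic_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a network for visualization
#'
#' GraphML preserves the edge `type` and `vesicles` attributes; DOT is a
#' plain topology export. Both are export-only conveniences — JSON
#' ([write_network()]) is the canonical lossless format.
#'
#' @param net a `traffic_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_dot <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "dot")
  invisible(path)
}

#' Serialize an orbit to JSON
#'
#' @param orbit an [run_to_orbit()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_orbit <- function(orbit, path) {
  obj <- list(
    states = orbit$states, period = orbit$period,
    steps_to_orbit = orbit$steps_to_orbit, reached = orbit$reached,
    homotypic_types = orbit$homotypic_types,
    degenerate = orbit$degenerate, N = orbit$rules_N
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_orbit
#' @export
read_orbit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- obj$states
  if (is.matrix(states)) states <- lapply(seq_len(nrow(states)), function(i) states[i, ])
  if (!is.list(states)) states <- list(states)
  structure(
    list(
      states = lapply(states, as.integer),
      period = as.integer(obj$period),
      steps_to_orbit = as.integer(obj$steps_to_orbit),
      reached = as.logical(obj$reached),
      homotypic_types = as.integer(obj$homotypic_types),
      degenerate = as.logical(obj$degenerate),
      rules_N = as.integer(obj$N)
    ),
    class = "orbit"
  )
}
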