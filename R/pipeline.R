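#' End-to-end homeostatic-network pipeline
#'
#' Orchestrates the full workflow: parameter sweep, per-network summary
#' tables, motif census, shuffled-null motif/chain census, and (optional)
#' spatial layout of the larger networks. Each stage writes its outputs
#' under `out_dir` and is skipped on re-runs when its output file already
#' exists, so a partially completed pipeline can be resumed; a manifest
#' JSON records the seeds, configuration and per-stage counts needed to
#' reproduce every artifact.
#'
#' @param out_dir output directory (created if needed).
#' @param grid a [sweep_grid()]; the reduced N = 7 grid by default.
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param shuffle_replicates shuffled nulls per network in the null
#'   census (the full-scale analysis uses 1000; the default here is a
#'   light 10 — configure up for production runs).
#' @param layout_networks how many networks with `min_layout_nodes` or
#'   more compartments to lay out (0 disables the stage).
#' @param min_layout_nodes compartment threshold for the layout stage.
#' @param progress print progress messages.
#' @return the manifest, invisibly.
#' @export
pipeline_run <- function(out_dir, grid = sweep_grid(), seed = 1L,
                         shuffle_replicates = 10L,
                         layout_networks = 30L, min_layout_nodes = 10L,
                         progress = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    runs = file.path(out_dir, "sweep_runs.csv"),
    summary = file.path(out_dir, "network_summary.csv"),
    motifs = file.path(out_dir, "motif_census.csv"),
    null = file.path(out_dir, "null_census.csv"),
    chains = file.path(out_dir, "chain_lengths.csv"),
    layout = file.path(out_dir, "layout_metrics.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4L)
  manifest <- list(
    package = "vesnet",
    version = as.character(utils::packageVersion("vesnet")),
    seed = seed, stage_seeds = stage_seeds,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    grid = list(N = unique(grid$N), A = unique(grid$A),
                g = unique(grid$g), f = unique(grid$f),
                replicates = attr(grid, "replicates")),
    stages = list()
  )

  sweep <- NULL
  need_sweep <- !file.exists(paths$runs) || !file.exists(paths$summary) ||
    !file.exists(paths$motifs) || !file.exists(paths$null) ||
    !file.exists(paths$chains) ||
    (layout_networks > 0L && !file.exists(paths$layout))
  if (need_sweep) {
    sweep <- run_sweep(grid, seed = stage_seeds[1L], progress = progress)
  }

  if (!file.exists(paths$runs)) {
    utils::write.csv(sweep$runs, paths$runs, row.names = FALSE)
  }
  manifest$stages$sweep <- c(list(file = paths$runs),
                             if (!is.null(sweep)) summary(sweep))

  if (!file.exists(paths$summary) || !file.exists(paths$chains)) {
    summ <- summarize_networks(sweep)
    chains <- data.frame(
      network = rep(summ$network, lengths(summ$chain_lengths)),
      length = unlist(summ$chain_lengths)
    )
    summ$chain_lengths <- NULL
    utils::write.csv(summ, paths$summary, row.names = FALSE)
    utils::write.csv(chains, paths$chains, row.names = FALSE)
  }
  manifest$stages$analyze <- list(files = c(paths$summary, paths$chains))

  if (!file.exists(paths$motifs)) {
    catalog <- motif_catalog()
    census <- motif_census(sweep$networks, catalog)
    utils::write.csv(census, paths$motifs, row.names = FALSE)
    manifest$stages$motifs <- list(file = paths$motifs,
                                   catalog_size = nrow(catalog))
  }

  if (!file.exists(paths$null)) {
    set.seed(stage_seeds[2L])
    if (!exists("catalog", inherits = FALSE)) catalog <- motif_catalog()
    shuffled <- list()
    for (net in sweep$networks) {
      for (rep in seq_len(shuffle_replicates)) {
        shuffled[[length(shuffled) + 1L]] <- shuffle_network(net)
      }
    }
    census <- motif_census(shuffled, catalog)
    utils::write.csv(census, paths$null, row.names = FALSE)
    manifest$stages$null <- list(file = paths$null,
                                 replicates = shuffle_replicates)
  }

  if (layout_networks > 0L && !file.exists(paths$layout)) {
    set.seed(stage_seeds[3L])
    sizes <- vapply(sweep$networks, function(n) length(n$nodes), integer(1))
    big <- which(sizes >= min_layout_nodes)
    if (length(big) > layout_networks) {
      big <- sort(sample(big, layout_networks))
    }
    rows <- lapply(big, function(k) {
      net <- sweep$networks[[k]]
      lay <- optimize_layout(net)
      data.frame(network = names(sweep$networks)[k],
                 n_compartments = length(net$nodes),
                 energy = lay$energy,
                 stacking = stacking_metric(lay, net),
                 stacking_shuffled = shuffled_stacking_metric(lay, net))
    })
    utils::write.csv(do.call(rbind, rows), paths$layout, row.names = FALSE)
    manifest$stages$layout <- list(file = paths$layout,
                                   n_networks = length(big))
  }

  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
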