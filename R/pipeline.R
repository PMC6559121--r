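# End-to-end orchestration: build -> connectivity -> enrichment ->
# subnetwork -> bridge -> mediators -> hits, from one configuration, with
# every stage output written to disk and hashed into a manifest.

#' Analysis configuration with the standard defaults
#'
#' Collects every tunable of the pipeline in one list. The numeric
#' defaults are the standard operating values of the analysis: 500
#' distance-matched random set pairs, top 5% neighbour-enrichment
#' qualification, at least 3 interactions with at least 2 sets, top 25%
#' bridge-score mediators, 20-cell image QC, 10,000 permutations and a
#' 0.05 significance level.
#'
#' Inputs are either file paths (`edges`, `locations`, `set_files` — a
#' named vector of one-identifier-per-line files, `annotations`) or, when
#' `edges` is `NULL`, a synthetic network generated from the `synthetic`
#' sub-list (arguments of [generate_network()]).
#'
#' @param anchor Anchor protein (default `"CFTR"`).
#' @param factors Stability-factor proteins paired with the anchor for
#'   bridge scoring.
#' @param edges,locations,set_files,annotations Optional input file paths.
#' @param synthetic List of [generate_network()] arguments used when
#'   `edges` is `NULL`.
#' @param n_random,top_fraction,min_cross_interactions,min_sets
#'   Connectivity / enrichment parameters.
#' @param mediator_top_fraction Bridge-score top fraction.
#' @param min_cells,n_perm,alpha Screen-statistics parameters.
#' @param seed Integer seed governing every stochastic stage.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(anchor = "CFTR",
                            factors = c("EPAC1", "NHERF1", "EZR", "SYK"),
                            edges = NULL, locations = NULL,
                            set_files = NULL, annotations = NULL,
                            synthetic = list(),
                            n_random = 500L, top_fraction = 0.05,
                            min_cross_interactions = 3L, min_sets = 2L,
                            mediator_top_fraction = 0.25,
                            min_cells = 20L, n_perm = 10000L,
                            alpha = 0.05, seed = 1L) {
  structure(list(
    anchor = anchor, factors = factors,
    edges = edges, locations = locations, set_files = set_files,
    annotations = annotations, synthetic = synthetic,
    n_random = as.integer(n_random), top_fraction = top_fraction,
    min_cross_interactions = as.integer(min_cross_interactions),
    min_sets = as.integer(min_sets),
    mediator_top_fraction = mediator_top_fraction,
    min_cells = as.integer(min_cells), n_perm = as.integer(n_perm),
    alpha = alpha, seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Missing fields take the [analysis_config()] defaults.
#'
#' @param path YAML file path.
#' @return List of class `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

# internal: deterministic TSV writer for stage outputs.
write_stage <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full network-analysis pipeline
#'
#' Executes the stages in order — network build, anchor distances,
#' pairwise set connectivity with matched randomisation, specific-neighbour
#' enrichment, anchor subnetwork assembly, bridge scores, strong-mediator
#' selection, and the hit-filter cascade — writing one TSV per stage into
#' `out_dir` plus a `manifest.tsv` with the MD5 hash of every output and a
#' `config.yaml` echo of all parameters. Rerunning with an identical
#' configuration reproduces identical hashes.
#'
#' @param config An [analysis_config()] (or path to a YAML file for
#'   [read_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the stage results and the manifest data
#'   frame.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  # stage 1: network ------------------------------------------------------
  if (!is.null(config$edges)) {
    pairs <- read_edge_list(config$edges)
    locations <- if (!is.null(config$locations)) {
      utils::read.delim(config$locations, header = FALSE,
                        col.names = c("protein", "compartment"),
                        stringsAsFactors = FALSE)
    } else NULL
    net <- build_network(pairs, locations, provenance = config$edges)
    sets <- lapply(config$set_files, readLines)
    names(sets) <- names(config$set_files)
    bridges <- character(0)
  } else {
    args <- config$synthetic
    args$anchor <- config$anchor
    args$bridge_factors <- config$factors
    args$seed <- config$seed
    gen <- do.call(generate_network, args)
    net <- gen$network
    sets <- gen$sets
    bridges <- gen$bridges
  }
  if (length(sets) < 2L) stop("the pipeline needs at least two interactor sets")
  f <- file.path(out_dir, "01_network.tsv")
  write_network(net, f); files <- c(files, f)

  # stage 2: connectivity vs matched random sets -------------------------
  profile <- shortest_distances(net, config$anchor)
  conn <- connectivity_table(net, profile, sets,
                             n_random = config$n_random,
                             seed = config$seed)
  f <- file.path(out_dir, "02_connectivity.tsv")
  write_stage(conn, f); files <- c(files, f)

  # stage 3: specific common neighbours ----------------------------------
  enr <- select_specific_neighbors(
    net, sets, top_fraction = config$top_fraction,
    min_cross_interactions = config$min_cross_interactions,
    min_sets = config$min_sets
  )
  f <- file.path(out_dir, "03_specific_neighbors.tsv")
  write_stage(enr$selected, f); files <- c(files, f)

  # stage 4: anchor subnetwork -------------------------------------------
  anchors <- c(config$anchor, intersect(config$factors,
                                        igraph::V(net)$name))
  candidates <- unique(c(enr$selected$candidate, unname(bridges)))
  sub <- assemble_subnetwork(net, anchors, candidates)
  f <- file.path(out_dir, "04_subnetwork.tsv")
  write_network(sub, f); files <- c(files, f)

  # stage 5: bridge scores per anchor-factor pair ------------------------
  present <- intersect(config$factors, igraph::V(sub)$name)
  if (length(present) == 0L) stop("no stability factor in the subnetwork")
  score_tabs <- lapply(present, function(fac) {
    tab <- bridge_scores(sub, config$anchor, fac)
    tab$pair <- paste(config$anchor, fac, sep = "-")
    tab
  })
  scores <- do.call(rbind, score_tabs)
  f <- file.path(out_dir, "05_bridge_scores.tsv")
  write_stage(scores, f); files <- c(files, f)

  # stage 6: strong mediators --------------------------------------------
  med <- select_strong_mediators(scores,
                                 top_fraction = config$mediator_top_fraction)
  f <- file.path(out_dir, "06_mediators.tsv")
  write_stage(med$mediators, f); files <- c(files, f)

  # stage 7: hit-filter cascade ------------------------------------------
  ann <- if (!is.null(config$annotations)) {
    if (is.character(config$annotations)) read_annotations(config$annotations)
    else config$annotations
  } else {
    generate_annotations(enr$selected$candidate, seed = config$seed)
  }
  hits <- apply_filters(enr$selected, ann, filter_config())
  f <- file.path(out_dir, "07_hits.tsv")
  write_stage(hits$hits, f); files <- c(files, f)

  # manifest ---------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- data.frame(
    stage = sub("\\.tsv$", "", basename(files)),
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  write_stage(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(network = net, profile = profile, connectivity = conn,
                 neighbors = enr, subnetwork = sub, bridge = scores,
                 mediators = med, hits = hits, manifest = manifest))
}
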