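# Synthetic data with planted ground truth: networks with anchored
# interactor sets and bridge nodes, screen matrices with planted effects,
# and random annotation tables. Every generator is a pure function of its
# arguments and seed.

#' Generate a synthetic interaction network with planted structure
#'
#' Produces a connected random network emulating the structure the
#' analysis assumes: an anchor protein, interactor sets enriched in the
#' anchor's network neighbourhood, optional extra edges within and between
#' sets, and optional planted bridge nodes. The base graph is
#' Erdos-Renyi with the requested mean degree (a deliberately simple null;
#' no attempt is made to mimic the degree distribution of curated
#' interactomes), made connected by attaching every stray component to the
#' anchor's component.
#'
#' Set members are drawn with fraction `near_fraction` from proteins
#' within distance 2 of the anchor and the rest from the remainder of the
#' network, mimicking sets selected by co-precipitation with the anchor.
#' `internal_boost`/`cross_boost` add edges among members of the same set
#' / between members of different sets with the given per-pair probability,
#' planting the connectivity signal the randomisation test is meant to
#' detect.
#'
#' Each entry of `bridge_factors` adds two nodes: the named stability
#' factor and a bridge node `BR_<factor>`; the factor is attached to the
#' network exclusively through the bridge node, which also links to the
#' anchor. Every path from anchor to factor therefore passes through the
#' bridge node, which consequently attains the maximal bridge score for
#' that pair — a construction guarantee used by the recovery tests.
#'
#' @param n_nodes Number of base proteins (default 1000).
#' @param avg_degree Target mean degree of the base graph (default 8).
#' @param anchor Anchor protein identifier (default `"CFTR"`).
#' @param set_sizes Named integer vector of interactor-set sizes; the
#'   default plants five sets of 80 (about 400 candidates in all). Use
#'   `NULL` for no sets.
#' @param near_fraction Fraction of each set drawn from within distance 2
#'   of the anchor (default 0.5).
#' @param internal_boost Extra edge probability within each set (default
#'   0.02).
#' @param cross_boost Extra edge probability between members of different
#'   sets (default 0 — no planted cross-connectivity).
#' @param bridge_factors Character vector of stability-factor names to
#'   plant behind bridge nodes (default none).
#' @param seed Optional integer seed.
#' @return List with `network` (igraph), `anchor`, `sets` (named list of
#'   member vectors), `bridges` (named character vector factor -> bridge
#'   node).
#' @export
generate_network <- function(n_nodes = 1000L, avg_degree = 8,
                             anchor = "CFTR",
                             set_sizes = c(wt = 80L, rescued = 80L,
                                           EPAC = 80L, pep_py = 80L,
                                           pep_wt = 80L),
                             near_fraction = 0.5,
                             internal_boost = 0.02,
                             cross_boost = 0,
                             bridge_factors = NULL,
                             seed = NULL) {
  set_seed_if(seed)
  n <- as.integer(n_nodes)
  stopifnot(n >= 10L, avg_degree > 0,
            is.null(set_sizes) || all(set_sizes < n))
  nodes <- c(anchor, sprintf("P%05d", seq_len(n - 1L)))
  g <- igraph::sample_gnp(n, min(1, avg_degree / (n - 1)))
  igraph::V(g)$name <- nodes

  # connectivity repair: attach each stray component to the anchor component
  cmp <- igraph::components(g)
  anchor_cmp <- cmp$membership[1L]
  anchor_members <- which(cmp$membership == anchor_cmp)
  stray <- setdiff(unique(cmp$membership), anchor_cmp)
  if (length(stray)) {
    new_edges <- unlist(lapply(stray, function(ci) {
      from <- which(cmp$membership == ci)
      c(from[sample.int(length(from), 1L)],
        anchor_members[sample.int(length(anchor_members), 1L)])
    }))
    g <- igraph::add_edges(g, new_edges)
  }

  d <- igraph::distances(g, v = 1L)[1L, ]
  near <- nodes[d >= 1 & d <= 2]
  far <- setdiff(nodes, c(anchor, near))

  sets <- list()
  if (!is.null(set_sizes) && length(set_sizes)) {
    stopifnot(!is.null(names(set_sizes)))
    sets <- lapply(as.integer(set_sizes), function(sz) {
      k_near <- min(round(near_fraction * sz), length(near))
      k_far <- sz - k_near
      if (k_far > length(far)) stop("set size infeasible for this network")
      c(near[sample.int(length(near), k_near)],
        far[sample.int(length(far), k_far)])
    })
    names(sets) <- names(set_sizes)

    boost_edges <- character(0)
    if (internal_boost > 0) {
      for (s in sets) {
        pr <- utils::combn(s, 2L)
        pick <- stats::runif(ncol(pr)) < internal_boost
        if (any(pick)) boost_edges <- c(boost_edges, pr[, pick])
      }
    }
    if (cross_boost > 0 && length(sets) >= 2L) {
      for (i in seq_len(length(sets) - 1L)) {
        for (j in seq(i + 1L, length(sets))) {
          pr <- expand.grid(a = setdiff(sets[[i]], sets[[j]]),
                            b = setdiff(sets[[j]], sets[[i]]),
                            stringsAsFactors = FALSE)
          pick <- stats::runif(nrow(pr)) < cross_boost
          if (any(pick)) {
            boost_edges <- c(boost_edges,
                             as.vector(rbind(pr$a[pick], pr$b[pick])))
          }
        }
      }
    }
    if (length(boost_edges)) g <- igraph::add_edges(g, boost_edges)
  }

  bridges <- character(0)
  if (!is.null(bridge_factors) && length(bridge_factors)) {
    bridge_nodes <- paste0("BR_", bridge_factors)
    g <- igraph::add_vertices(g, 2L * length(bridge_factors),
                              name = c(bridge_factors, bridge_nodes))
    # bridge -> factor and bridge -> anchor edges; the factor touches the
    # network only through its bridge node
    g <- igraph::add_edges(g, c(rbind(bridge_nodes, bridge_factors)))
    g <- igraph::add_edges(g, c(rbind(bridge_nodes, anchor)))
    bridges <- stats::setNames(bridge_nodes, bridge_factors)
  }

  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g$provenance <- "synthetic"
  list(network = g, anchor = anchor, sets = sets, bridges = bridges)
}

#' Generate a synthetic deviation-score screen matrix
#'
#' Emulates the replicate structure of the trafficking screen: a long
#' table of deviation scores for `n_sirnas` siRNAs, the three CFTR types
#' and `n_replicates` replicates. Unplanted cells are pure noise
#' (mean 0, SD `noise_sd`, matching normalised null deviation scores);
#' planted siRNAs add the requested per-type mean effects.
#'
#' @param n_sirnas Number of siRNAs (default 12).
#' @param n_replicates Replicates per siRNA and type (default 3).
#' @param cftr_types CFTR type labels (default wild type, mutant,
#'   corrector-rescued mutant).
#' @param planted Named list: siRNA label -> numeric vector of per-type
#'   mean deviation scores (same length/order as `cftr_types`). Labels not
#'   of the form `siRNA_k` are added to the matrix.
#' @param noise_sd Replicate noise SD (default 1, the null scale).
#' @param seed Optional integer seed.
#' @return Data frame `sirna`, `cftr_type`, `replicate`, `ds`, with the
#'   planted effect map in attribute `ground_truth`.
#' @export
generate_screen <- function(n_sirnas = 12L, n_replicates = 3L,
                            cftr_types = c("wt", "F508del",
                                           "F508del_VX809"),
                            planted = list(), noise_sd = 1,
                            seed = NULL) {
  set_seed_if(seed)
  labels <- sprintf("siRNA_%02d", seq_len(n_sirnas))
  labels <- union(labels, names(planted))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      cftr_type = cftr_types, sirna = labels,
                      stringsAsFactors = FALSE)[, 3:1]
  mu <- mapply(function(s, ty) {
    eff <- planted[[s]]
    if (is.null(eff)) 0 else eff[match(ty, cftr_types)]
  }, grid$sirna, grid$cftr_type)
  grid$ds <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  rownames(grid) <- NULL
  attr(grid, "ground_truth") <- planted
  grid
}

#' Generate a random protein annotation table
#'
#' Random annotations for hit-filter testing: expression levels drawn with
#' the given probabilities (remainder `not_available`), each keyword
#' assigned independently with its probability, and the two flags set with
#' probabilities `p_prior` / `p_experimental`.
#'
#' @param proteins Character vector of protein identifiers.
#' @param p_expression Named probabilities for levels `low`, `medium`,
#'   `high` (must sum to at most 1; the rest is `not_available`).
#' @param keyword_probs Named numeric vector: keyword -> probability.
#' @param p_prior Probability of the `prior_interactor` flag.
#' @param p_experimental Probability of the `in_experimental_sets` flag.
#' @param seed Optional integer seed.
#' @return Annotation data frame in the layout of [read_annotations()].
#' @export
generate_annotations <- function(proteins,
                                 p_expression = c(low = 0.25,
                                                  medium = 0.4,
                                                  high = 0.25),
                                 keyword_probs = c(nuclear = 0.1,
                                                   ribosomal = 0.05),
                                 p_prior = 0.1, p_experimental = 0.1,
                                 seed = NULL) {
  set_seed_if(seed)
  stopifnot(sum(p_expression) <= 1)
  n <- length(proteins)
  levels <- c(names(p_expression), "not_available")
  probs <- c(p_expression, 1 - sum(p_expression))
  expr <- sample(levels, n, replace = TRUE, prob = probs)
  kw <- vapply(seq_len(n), function(i) {
    hit <- names(keyword_probs)[stats::runif(length(keyword_probs)) <
                                  keyword_probs]
    paste(hit, collapse = ";")
  }, character(1))
  data.frame(
    protein = proteins,
    expression_level = expr,
    keywords = kw,
    prior_interactor = stats::runif(n) < p_prior,
    in_experimental_sets = stats::runif(n) < p_experimental,
    stringsAsFactors = FALSE
  )
}
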