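# Connectivity between interactor sets and its significance against
# distance-matched random node sets.

# internal: the three connectivity statistics on integer index sets.
# direct interactions are counted as edge-set cardinality: the number of
# network edges with one endpoint in A and the other in B, an edge internal
# to the overlap counted once.
conn_stats_idx <- function(ai, ia, ib) {
  n <- ai$n
  mem_a <- logical(n); mem_a[ia] <- TRUE
  mem_b <- logical(n); mem_b[ib] <- TRUE

  overlap <- sum(mem_a & mem_b)

  # ordered incidences u in A with neighbour in B; edges with both ends in
  # the overlap are seen from both sides, so subtract them once
  inc <- sum(vapply(ai$adj[ia], function(nb) sum(mem_b[nb]), numeric(1)))
  both <- which(mem_a & mem_b)
  internal <- if (length(both)) {
    sum(vapply(ai$adj[both],
               function(nb) sum(mem_a[nb] & mem_b[nb]), numeric(1))) / 2
  } else 0
  direct <- inc - internal

  # proteins adjacent to at least one member of each set (their own
  # membership is irrelevant: adjacency, not membership, counts)
  adj_a <- logical(n); adj_a[unlist(ai$adj[ia], use.names = FALSE)] <- TRUE
  adj_b <- logical(n); adj_b[unlist(ai$adj[ib], use.names = FALSE)] <- TRUE
  common <- sum(adj_a & adj_b)

  c(overlap = overlap, direct_interactions = direct,
    common_neighbors = common)
}

#' Connectivity statistics between two interactor sets
#'
#' The three measures of how strongly two protein sets are wired together
#' on the network: the number of shared members (overlap), the number of
#' network edges with one endpoint in each set (direct interactions; an
#' edge joining two proteins that belong to both sets is counted once), and
#' the number of common direct neighbours — proteins adjacent to at least
#' one member of each set, whether or not they are members themselves.
#' All three are symmetric in the two sets.
#'
#' @param net Interaction network (igraph), as from [build_network()].
#' @param a,b Character vectors of protein identifiers. Members absent from
#'   the network are dropped with a message; an empty mapped set is an
#'   error.
#' @return Named numeric vector with elements `overlap`,
#'   `direct_interactions`, `common_neighbors`.
#' @export
connectivity_stats <- function(net, a, b) {
  ai <- adjacency_index(net)
  ia <- map_members(ai, a, "a")
  ib <- map_members(ai, b, "b")
  conn_stats_idx(ai, ia, ib)
}

# internal: per-distance stratum populations (integer indices), anchor
# excluded. `d` is the distance vector aligned with ai$nodes.
distance_strata <- function(ai, profile) {
  d <- profile$distances[ai$nodes]
  if (anyNA(d)) stop("distance profile does not cover the whole network")
  anchor_idx <- match(profile$anchor, ai$nodes)
  idx <- setdiff(seq_len(ai$n), anchor_idx)
  split(idx, d[idx])
}

# internal: one matched draw. `need` is a table of required counts per
# distance (names are distances as character).
draw_matched_idx <- function(strata, need) {
  out <- vector("list", length(need))
  keys <- names(need)
  for (i in seq_along(need)) {
    pool <- strata[[keys[i]]]
    k <- need[[i]]
    if (is.null(pool) || length(pool) < k) {
      stop("distance stratum ", keys[i], " has ", length(pool),
           " proteins but ", k, " are required")
    }
    out[[i]] <- pool[sample.int(length(pool), k)]
  }
  unlist(out, use.names = FALSE)
}

#' Sample a distance-matched random protein set
#'
#' Draws a random set of proteins with exactly the same number of members
#' at each shortest-path distance from the anchor as a template set:
#' within each distance stratum, members are sampled uniformly without
#' replacement; the anchor itself is never sampled. This is the null model
#' for [connectivity_significance()]: the template sets were selected by
#' co-precipitation with the anchor, so random sets must share their
#' distance profile, not just their size.
#'
#' @param net Interaction network (igraph).
#' @param profile Distance profile from [shortest_distances()], anchored at
#'   the protein the template sets were derived from.
#' @param template Character vector of template set members (all must be in
#'   the network and at finite distance from the anchor).
#' @param seed Optional integer seed for a reproducible draw.
#' @return Character vector of sampled protein identifiers, same length and
#'   per-stratum counts as the template.
#' @export
sample_matched_set <- function(net, profile, template, seed = NULL) {
  set_seed_if(seed)
  ai <- adjacency_index(net)
  it <- map_members(ai, template, "template")
  strata <- distance_strata(ai, profile)
  need <- table(profile$distances[ai$nodes][it])
  ai$nodes[draw_matched_idx(strata, need)]
}

#' Significance of interactor-set connectivity by matched randomisation
#'
#' Compares the observed connectivity statistics of two interactor sets
#' ([connectivity_stats()]) with their distribution over `n_random` pairs
#' of distance-matched random sets. In each iteration both sets are
#' re-drawn by [sample_matched_set()]'s stratified sampler (set
#' `resample_both = FALSE` to keep `b` fixed and randomise only `a`). The
#' empirical p-value of each statistic is the fraction of random pairs
#' whose value is greater than *or equal to* the observed one — ties count
#' as exceeding, so p is never understated. A zero exceedance count is
#' reported with the label `"<1/n_random"` alongside the raw fraction,
#' mirroring the resolution floor of the randomisation.
#'
#' @inheritParams sample_matched_set
#' @param a,b Character vectors of set members.
#' @param n_random Number of random set pairs (default 500).
#' @param resample_both Randomise both sets each iteration (default) or
#'   only `a`.
#' @param seed Optional integer seed.
#' @return Object of class `connectivity_significance`: a list with
#'   `observed`, `expected` (means over random pairs), `p_values` (raw
#'   fractions), `p_labels` (with the `<1/n_random` floor applied),
#'   `n_random` and `seed`.
#' @export
connectivity_significance <- function(net, profile, a, b, n_random = 500L,
                                      resample_both = TRUE, seed = NULL) {
  set_seed_if(seed)
  n_random <- as.integer(n_random)
  stopifnot(n_random >= 1L)
  ai <- adjacency_index(net)
  ia <- map_members(ai, a, "a")
  ib <- map_members(ai, b, "b")
  d <- profile$distances[ai$nodes]
  if (any(!is.finite(d[c(ia, ib)]))) {
    stop("all set members must be at finite distance from the anchor")
  }
  strata <- distance_strata(ai, profile)
  need_a <- table(d[ia])
  need_b <- table(d[ib])

  observed <- conn_stats_idx(ai, ia, ib)
  exceed <- c(0, 0, 0)
  total <- c(0, 0, 0)
  for (r in seq_len(n_random)) {
    ra <- draw_matched_idx(strata, need_a)
    rb <- if (resample_both) draw_matched_idx(strata, need_b) else ib
    st <- conn_stats_idx(ai, ra, rb)
    exceed <- exceed + (st >= observed)
    total <- total + st
  }
  p <- exceed / n_random
  names(p) <- names(observed)
  labels <- ifelse(exceed == 0, paste0("<", format(1 / n_random)),
                   format(p))
  names(labels) <- names(observed)
  structure(
    list(observed = observed, expected = total / n_random,
         p_values = p, p_labels = labels,
         n_random = n_random, seed = seed,
         resample_both = resample_both),
    class = "connectivity_significance"
  )
}

#' @export
print.connectivity_significance <- function(x, ...) {
  cat("Interactor-set connectivity vs", x$n_random,
      "distance-matched random set pairs\n")
  out <- data.frame(
    statistic = names(x$observed),
    observed = unname(x$observed),
    expected = round(unname(x$expected), 1),
    p = unname(x$p_labels),
    row.names = NULL
  )
  print(out)
  invisible(x)
}

#' Pairwise connectivity table for a list of interactor sets
#'
#' Runs [connectivity_significance()] for every unordered pair of sets and
#' assembles the results in a long table (one row per set pair and
#' statistic): the layout of the published connectivity tables for the
#' five CFTR interactor sets.
#'
#' @inheritParams connectivity_significance
#' @param sets Named list of character vectors of set members.
#' @return Data frame with columns `set_a`, `set_b`, `statistic`,
#'   `observed`, `expected`, `p`, `p_label`.
#' @export
connectivity_table <- function(net, profile, sets, n_random = 500L,
                               seed = NULL) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  set_seed_if(seed)
  labels <- names(sets)
  rows <- list()
  for (i in seq_len(length(sets) - 1L)) {
    for (j in seq(i + 1L, length(sets))) {
      res <- connectivity_significance(net, profile, sets[[i]], sets[[j]],
                                       n_random = n_random)
      rows[[length(rows) + 1L]] <- data.frame(
        set_a = labels[i], set_b = labels[j],
        statistic = names(res$observed),
        observed = unname(res$observed),
        expected = unname(res$expected),
        p = unname(res$p_values),
        p_label = unname(res$p_labels),
        row.names = NULL
      )
    }
  }
  do.call(rbind, rows)
}
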