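# Specific common neighbours: per-candidate hypergeometric neighbour
# enrichment, top-fraction qualification, cross-set interaction thresholds
# and rank-sum ordering.

#' Hypergeometric neighbour-enrichment test for one candidate
#'
#' Tests whether the direct neighbours of a candidate protein are enriched
#' in members of an interactor set. The neighbourhood of the candidate is
#' treated as a draw of `degree` proteins from the network universe
#' excluding the candidate itself (a protein is not its own neighbour):
#' population `N - 1`, successes `|members \ {candidate}|`, draws the
#' candidate's degree, and the reported p is the upper tail
#' `P(X >= overlap)`. A candidate sharing no neighbour with the set gets
#' p = 1.
#'
#' @param net Interaction network (igraph).
#' @param candidate Protein identifier in the network.
#' @param members Character vector of set members.
#' @param set_label Label stored in the output row.
#' @return One-row data frame: `candidate`, `set_label`, `degree`,
#'   `set_size` (members on the network, candidate excluded), `overlap`,
#'   `p`.
#' @export
neighbor_enrichment_p <- function(net, candidate, members,
                                  set_label = "set") {
  ai <- adjacency_index(net)
  ci <- match(candidate, ai$nodes)
  if (is.na(ci)) stop("candidate '", candidate, "' is not in the network")
  nb <- ai$adj[[ci]]
  if (length(nb) == 0L) stop("candidate '", candidate, "' is isolated")
  im <- setdiff(map_members(ai, members, set_label), ci)
  m <- length(im)
  overlap <- sum(nb %in% im)
  p <- stats::phyper(overlap - 1L, m, ai$n - 1L - m, length(nb),
                     lower.tail = FALSE)
  data.frame(candidate = candidate, set_label = set_label,
             degree = length(nb), set_size = m, overlap = overlap,
             p = p, stringsAsFactors = FALSE)
}

# internal: vectorised enrichment of every network protein against one set.
# Returns a data.frame over the tested candidates (>= 1 neighbour in the
# set). Set members are eligible candidates; for a candidate that is
# itself a member, the success count excludes it.
enrich_all_idx <- function(ai, im, set_label) {
  n <- ai$n
  mem <- logical(n); mem[im] <- TRUE
  overlap <- vapply(ai$adj, function(nb) sum(mem[nb]), numeric(1))
  degree <- lengths(ai$adj)
  m_eff <- sum(mem) - as.numeric(mem)      # members excluding the candidate
  tested <- which(overlap >= 1)
  p <- stats::phyper(overlap[tested] - 1, m_eff[tested],
                     (n - 1) - m_eff[tested], degree[tested],
                     lower.tail = FALSE)
  data.frame(candidate = ai$nodes[tested], set_label = set_label,
             degree = degree[tested], set_size = m_eff[tested],
             overlap = overlap[tested], p = p,
             stringsAsFactors = FALSE)
}

#' Select specific common neighbours of several interactor sets
#'
#' The multiple-testing device used instead of a p-value cutoff: for each
#' set, every protein with at least one neighbour in the set is tested
#' ([neighbor_enrichment_p()]), and the fraction `top_fraction` with the
#' lowest p-values qualifies as a specific neighbour of that set (the first
#' `ceiling(top_fraction * n_tested)` candidates; boundary ties all
#' qualify). A protein is then *selected* if it qualified for at least one
#' set and has at least `min_cross_interactions` direct interactions with
#' each of `min_sets` or more of the sets (set
#' `require_min_sets_qualified = TRUE` for the stricter reading that
#' demands qualification in `min_sets` sets).
#'
#' Selected proteins are ordered by a rank sum over their qualified sets
#' only. Within each set, candidates are mid-ranked by p; with the default
#' `rank_direction = "high_best"` the smallest p receives the largest rank
#' (`n_tested`), so the rank sum rewards both significance and breadth
#' across sets and "higher rank sum" means a better candidate.
#' `rank_direction = "low_best"` flips the convention (smallest p = rank 1,
#' ordering ascending).
#'
#' @param net Interaction network (igraph).
#' @param sets Named list (>= 2) of character vectors of set members.
#' @param top_fraction Fraction of tested candidates qualifying per set
#'   (default 0.05).
#' @param min_cross_interactions Minimum direct interactions with a set for
#'   it to count towards `min_sets` (default 3).
#' @param min_sets Minimum number of sets meeting the interaction threshold
#'   (default 2).
#' @param rank_direction `"high_best"` (default) or `"low_best"`; see
#'   Details.
#' @param require_min_sets_qualified If `TRUE`, selection additionally
#'   requires top-fraction qualification in at least `min_sets` sets.
#' @return Object of class `specific_neighbors`: list with `selected` (data
#'   frame: `candidate`, `qualified_sets`, `n_qualified_sets`, `rank_sum`,
#'   `overall_rank`, ordered best first) and `records` (per-set enrichment
#'   data frame with `rank` and `qualified` columns).
#' @export
select_specific_neighbors <- function(net, sets, top_fraction = 0.05,
                                      min_cross_interactions = 3L,
                                      min_sets = 2L,
                                      rank_direction = c("high_best",
                                                         "low_best"),
                                      require_min_sets_qualified = FALSE) {
  rank_direction <- match.arg(rank_direction)
  stopifnot(length(sets) >= 2L, !is.null(names(sets)),
            top_fraction > 0, top_fraction <= 1)
  ai <- adjacency_index(net)

  records <- lapply(names(sets), function(lbl) {
    im <- map_members(ai, sets[[lbl]], lbl)
    rec <- enrich_all_idx(ai, im, lbl)
    n_tested <- nrow(rec)
    k_q <- ceiling(top_fraction * n_tested)
    thr <- sort(rec$p, partial = k_q)[k_q]
    rec$qualified <- rec$p <= thr
    asc <- rank(rec$p, ties.method = "average")
    rec$rank <- if (rank_direction == "high_best") n_tested + 1 - asc else asc
    rec
  })
  records <- do.call(rbind, records)

  # per-candidate bookkeeping across sets
  cand <- sort(unique(records$candidate))
  qual <- records[records$qualified, , drop = FALSE]
  cross_ok <- records[records$overlap >= min_cross_interactions, ,
                      drop = FALSE]
  n_cross <- table(factor(cross_ok$candidate, levels = cand))
  n_qual <- table(factor(qual$candidate, levels = cand))
  need_qual <- if (require_min_sets_qualified) min_sets else 1L
  selected <- cand[n_qual >= need_qual & n_cross >= min_sets]

  if (length(selected) == 0L) {
    warning("no candidate satisfies the selection thresholds")
    sel_df <- data.frame(candidate = character(), qualified_sets = character(),
                         n_qualified_sets = integer(), rank_sum = numeric(),
                         overall_rank = integer(), stringsAsFactors = FALSE)
  } else {
    qsel <- qual[qual$candidate %in% selected, , drop = FALSE]
    qsel <- qsel[order(qsel$candidate, qsel$set_label), , drop = FALSE]
    rank_sum <- tapply(qsel$rank, qsel$candidate, sum)
    qualified_sets <- tapply(qsel$set_label, qsel$candidate,
                             function(s) paste(s, collapse = ","))
    nq <- tapply(qsel$set_label, qsel$candidate, length)
    sel_df <- data.frame(
      candidate = names(rank_sum),
      qualified_sets = unname(qualified_sets[names(rank_sum)]),
      n_qualified_sets = as.integer(nq[names(rank_sum)]),
      rank_sum = unname(rank_sum),
      stringsAsFactors = FALSE
    )
    o <- if (rank_direction == "high_best") {
      order(-sel_df$rank_sum, sel_df$candidate, method = "radix")
    } else {
      order(sel_df$rank_sum, sel_df$candidate, method = "radix")
    }
    sel_df <- sel_df[o, , drop = FALSE]
    sel_df$overall_rank <- seq_len(nrow(sel_df))
    rownames(sel_df) <- NULL
  }
  structure(list(selected = sel_df, records = records,
                 top_fraction = top_fraction,
                 min_cross_interactions = min_cross_interactions,
                 min_sets = min_sets, rank_direction = rank_direction),
            class = "specific_neighbors")
}

#' @export
print.specific_neighbors <- function(x, ...) {
  cat(nrow(x$selected), "specific common neighbours selected",
      "(top fraction", x$top_fraction, ", >=",
      x$min_cross_interactions, "interactions with >=", x$min_sets,
      "sets)\n")
  print(head(x$selected, 10))
  if (nrow(x$selected) > 10) cat("...\n")
  invisible(x)
}
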