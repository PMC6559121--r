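# Anchor subnetwork assembly and the short-path bridge score.
#
# The bridge score of a candidate node for an anchor pair (a, b) is the
# weighted sum of the fractions of simple paths of length 2, 3 and 4
# between a and b that pass through the candidate, with weights 1, 0.5 and
# 0.25: mediation of shorter paths counts more. Paths are simple (no node
# revisited); a length with no path at all contributes a fraction of 0.

#' Assemble the anchor subnetwork
#'
#' Induces the subgraph on the anchors (e.g. CFTR plus its stability
#' factors) together with the candidate proteins, then keeps the connected
#' component containing the first anchor. Candidates with no connection to
#' that component are dropped with a message.
#'
#' @param net Interaction network (igraph).
#' @param anchors Character vector of anchor proteins; all must be present
#'   in `net`, and the first defines the component that is kept.
#' @param candidates Character vector of candidate proteins (members absent
#'   from `net` are ignored).
#' @return Connected igraph subnetwork.
#' @export
assemble_subnetwork <- function(net, anchors, candidates) {
  nodes <- igraph::V(net)$name
  missing_anchor <- setdiff(anchors, nodes)
  if (length(missing_anchor)) {
    stop("anchor(s) not in network: ",
         paste(missing_anchor, collapse = ", "))
  }
  keep <- intersect(unique(c(anchors, candidates)), nodes)
  sub <- igraph::induced_subgraph(net, keep)
  cmp <- igraph::components(sub)
  first <- cmp$membership[match(anchors[1L], igraph::V(sub)$name)]
  dropped <- sum(cmp$membership != first)
  if (dropped > 0L) {
    message(dropped, " proteins not connected to '", anchors[1L],
            "' dropped from the subnetwork")
  }
  igraph::induced_subgraph(sub, which(cmp$membership == first))
}

#' Count simple paths of a fixed short length between two nodes
#'
#' Enumerates the simple paths (no repeated nodes) with exactly `L` edges
#' between the two proteins of an anchor pair, and for every intermediate
#' node the number of such paths containing it. The endpoints are never
#' intermediates. Only `L` in 2, 3, 4 is supported — the lengths entering
#' the bridge score.
#'
#' @param sub Subnetwork (igraph), as from [assemble_subnetwork()].
#' @param a,b Anchor pair protein identifiers (distinct, in `sub`).
#' @param L Path length in edges: 2, 3 or 4.
#' @return List with `total` (path count) and `per_node` (named numeric
#'   vector over all nodes; entry = number of length-`L` paths containing
#'   that node as an intermediate).
#' @export
count_paths <- function(sub, a, b, L) {
  stopifnot(L %in% c(2L, 3L, 4L))
  if (a == b) stop("anchor pair must be two distinct proteins")
  ai <- adjacency_index(sub)
  ia <- match(a, ai$nodes)
  ib <- match(b, ai$nodes)
  if (is.na(ia) || is.na(ib)) stop("anchor pair not in subnetwork")
  adj <- ai$adj
  n <- ai$n
  per <- numeric(n)
  total <- 0

  na_ <- setdiff(adj[[ia]], ib)
  nb_ <- setdiff(adj[[ib]], ia)
  mem_b <- logical(n); mem_b[nb_] <- TRUE

  if (L == 2L) {
    mids <- intersect(adj[[ia]], adj[[ib]])
    mids <- setdiff(mids, c(ia, ib))
    total <- length(mids)
    per[mids] <- 1
  } else if (L == 3L) {
    for (x in na_) {
      ys <- adj[[x]]
      ys <- ys[mem_b[ys]]
      k <- length(ys)
      if (k) {
        total <- total + k
        per[x] <- per[x] + k
        per[ys] <- per[ys] + 1
      }
    }
  } else {
    for (x in na_) {
      for (y in adj[[x]]) {
        if (y == ia || y == ib) next
        zs <- adj[[y]]
        zs <- zs[mem_b[zs]]
        zs <- zs[zs != x]
        k <- length(zs)
        if (k) {
          total <- total + k
          per[x] <- per[x] + k
          per[y] <- per[y] + k
          per[zs] <- per[zs] + 1
        }
      }
    }
  }
  names(per) <- ai$nodes
  list(total = total, per_node = per)
}

#' Bridge scores of every candidate for one anchor pair
#'
#' Computes, for every node other than the two anchors, the fractions of
#' length-2, -3 and -4 simple paths between the anchors that contain the
#' node, and the weighted bridge score `f2 + 0.5 * f3 + 0.25 * f4`
#' (range 0 to 1.75). A path length with zero total contributes 0.
#'
#' @inheritParams count_paths
#' @return Data frame with columns `candidate`, `f2`, `f3`, `f4`, `score`,
#'   one row per non-anchor node.
#' @seealso [bridge_score()] for a single candidate,
#'   [select_strong_mediators()] for the top-fraction rule.
#' @export
bridge_scores <- function(sub, a, b) {
  p2 <- count_paths(sub, a, b, 2L)
  p3 <- count_paths(sub, a, b, 3L)
  p4 <- count_paths(sub, a, b, 4L)
  nodes <- setdiff(igraph::V(sub)$name, c(a, b))
  frac <- function(p) if (p$total > 0) p$per_node[nodes] / p$total else
    setNames(numeric(length(nodes)), nodes)
  f2 <- frac(p2); f3 <- frac(p3); f4 <- frac(p4)
  data.frame(candidate = nodes,
             f2 = unname(f2), f3 = unname(f3), f4 = unname(f4),
             score = unname(f2 + 0.5 * f3 + 0.25 * f4),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bridge score of a single candidate
#'
#' @inheritParams count_paths
#' @param candidate Protein identifier, distinct from both anchors.
#' @return One-row data frame as in [bridge_scores()], plus `pair_a` and
#'   `pair_b` columns.
#' @export
bridge_score <- function(sub, a, b, candidate) {
  if (candidate %in% c(a, b)) {
    stop("candidate must be distinct from the anchor pair")
  }
  if (!candidate %in% igraph::V(sub)$name) {
    stop("candidate '", candidate, "' is not in the subnetwork")
  }
  tab <- bridge_scores(sub, a, b)
  row <- tab[tab$candidate == candidate, , drop = FALSE]
  row$pair_a <- a
  row$pair_b <- b
  rownames(row) <- NULL
  row
}

#' Select strong mediators by the top-fraction bridge-score rule
#'
#' A candidate is a strong mediator for an anchor pair if its bridge score
#' is in the top `top_fraction` of all candidate scores for that pair:
#' the threshold is the `ceiling(top_fraction * n)`-th largest score and
#' boundary ties are included, so when all scores are equal every candidate
#' is strong. Input is a long table covering one or more pairs.
#'
#' @param scores Data frame with columns `candidate`, `pair` (label of the
#'   anchor pair) and `score`, e.g. stacked [bridge_scores()] outputs with
#'   a `pair` column added.
#' @param top_fraction Fraction defining "top" (default 0.25).
#' @return List with `records` (the input with a logical `strong` column)
#'   and `mediators` (data frame `candidate`, `pairs`, `n_pairs` for
#'   candidates strong for at least one pair).
#' @export
select_strong_mediators <- function(scores, top_fraction = 0.25) {
  stopifnot(all(c("candidate", "pair", "score") %in% names(scores)),
            top_fraction > 0, top_fraction <= 1)
  scores$strong <- FALSE
  for (p in unique(scores$pair)) {
    i <- which(scores$pair == p)
    s <- scores$score[i]
    k <- ceiling(top_fraction * length(s))
    thr <- sort(s, decreasing = TRUE)[k]
    scores$strong[i] <- s >= thr
  }
  strong <- scores[scores$strong, , drop = FALSE]
  if (nrow(strong)) {
    strong <- strong[order(strong$candidate, strong$pair), , drop = FALSE]
    med <- data.frame(
      candidate = unique(strong$candidate),
      stringsAsFactors = FALSE
    )
    med$pairs <- vapply(med$candidate, function(cc) {
      paste(strong$pair[strong$candidate == cc], collapse = ",")
    }, character(1))
    med$n_pairs <- vapply(med$candidate, function(cc) {
      sum(strong$candidate == cc)
    }, integer(1))
    rownames(med) <- NULL
  } else {
    med <- data.frame(candidate = character(), pairs = character(),
                      n_pairs = integer(), stringsAsFactors = FALSE)
  }
  list(records = scores, mediators = med)
}
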