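# Independent oracles, deliberately written with different algorithms than
# the package implementation so the two routes only agree if both are right.

# Exhaustive DFS enumeration of simple paths with exactly L edges between
# a and b. Returns list(total, per_node): per_node counts over intermediate
# nodes only.
oracle_count_paths <- function(g, a, b, L) {
  nbrs <- lapply(igraph::as_adj_list(g, mode = "all"), function(v) {
    igraph::V(g)$name[as.integer(v)]
  })
  names(nbrs) <- igraph::V(g)$name
  paths <- list()
  rec <- function(path) {
    last <- path[length(path)]
    if (length(path) - 1L == L) {
      if (last == b) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (last == b) return(invisible())   # b is terminal on a simple a-b path
    for (x in nbrs[[last]]) {
      if (!(x %in% path)) rec(c(path, x))
    }
  }
  rec(a)
  per <- table(unlist(lapply(paths, function(p) p[-c(1L, length(p))])))
  list(total = length(paths), per_node = per)
}

# Bridge score via the DFS oracle.
oracle_bridge_score <- function(g, a, b, candidate) {
  w <- c(`2` = 1, `3` = 0.5, `4` = 0.25)
  s <- 0
  for (L in 2:4) {
    cp <- oracle_count_paths(g, a, b, L)
    if (cp$total > 0) {
      k <- cp$per_node[candidate]
      if (!is.na(k)) s <- s + w[[as.character(L)]] * k / cp$total
    }
  }
  unname(s)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of every
# possible neighbour configuration: population of N items of which the
# first m are successes; draw k; P(successes >= q).
oracle_hyper_upper <- function(N, m, k, q) {
  draws <- utils::combn(N, k)
  mean(colSums(draws <= m) >= q)
}

# Connected components by union-find on an edge data frame.
oracle_components <- function(edges) {
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(edges))) {
    i <- find(match(edges[[1]][r], nodes))
    j <- find(match(edges[[2]][r], nodes))
    if (i != j) parent[j] <- i
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  split(nodes, roots)
}

# Connectivity statistics by literal brute force over nodes and edges.
oracle_conn_stats <- function(g, A, B) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  overlap <- length(intersect(A, B))
  direct <- sum(apply(el, 1, function(e) {
    (e[1] %in% A && e[2] %in% B) || (e[2] %in% A && e[1] %in% B)
  }))
  nb <- function(x) nodes[as.integer(igraph::neighbors(g, x))]
  common <- sum(vapply(nodes, function(x) {
    nx <- nb(x)
    length(intersect(nx, A)) > 0 && length(intersect(nx, B)) > 0
  }, logical(1)))
  c(overlap = overlap, direct_interactions = direct,
    common_neighbors = common)
}

# All-pairs shortest paths by Floyd-Warshall (vectorised over rows).
oracle_fw_distances <- function(g, anchor) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  D[el] <- 1
  D[el[, c(2, 1), drop = FALSE]] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  d <- D[match(anchor, igraph::V(g)$name), ]
  names(d) <- igraph::V(g)$name
  d
}
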