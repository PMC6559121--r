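# Small graph builders used across the suite.

# Undirected path graph over the given ids, in order.
path_graph <- function(ids) {
  igraph::make_graph(
    unlist(lapply(seq_len(length(ids) - 1L), function(i) ids[i:(i + 1L)])),
    directed = FALSE
  )
}

# Graph from an inline edge string: "A-B B-C ..."
graph_from_edges <- function(spec) {
  parts <- strsplit(strsplit(spec, "[[:space:]]+")[[1]], "-", fixed = TRUE)
  igraph::make_graph(unlist(parts), directed = FALSE)
}

# Random connected graph with named nodes: Erdos-Renyi, largest component,
# regenerated until it holds at least `min_n` nodes.
rand_connected_graph <- function(n, p, min_n = 6L) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
    cmp <- igraph::components(g)
    g <- igraph::induced_subgraph(g,
                                  which(cmp$membership == which.max(cmp$csize)))
    if (igraph::vcount(g) >= min_n) return(g)
  }
}

# The ten-node worked example for the neighbour-enrichment test: candidate
# "C" of degree 3 with 2 of its neighbours among a 4-member set.
enrichment_example_graph <- function() {
  graph_from_edges(
    "C-N1 C-N2 C-N3 N3-S3 S3-S4 S4-F1 F1-F2 F2-N1 F3-F2 F3-N2 F4-F3"
  )
}
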