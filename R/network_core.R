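# Operational interaction network: ingestion, cleaning, distances.
#
# Protein identifiers are opaque, case-sensitive strings (UniProt accessions
# or gene symbols); no identifier mapping is performed anywhere in the
# package.

#' Read a raw protein interaction edge list
#'
#' Reads a delimited two-column (or wider) interaction file verbatim:
#' duplicate rows, reciprocal rows and self-pairs are all preserved, since
#' cleaning is the job of [build_network()]. Lines starting with `#` and
#' blank lines are skipped.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default tab).
#' @param columns Integer vector of length 2 giving the columns holding the
#'   two interactor identifiers (default `c(1, 2)`, so extra columns such as
#'   confidence scores are ignored).
#' @param comment_char Lines whose first non-blank character is this are
#'   skipped.
#' @return A data frame with character columns `from` and `to`, one row per
#'   input interaction row.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC"), tf)
#' read_edge_list(tf)
#' @export
read_edge_list <- function(path, sep = "\t", columns = c(1L, 2L),
                           comment_char = "#") {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  stopifnot(length(columns) == 2L)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, comment_char)
  if (!any(keep)) stop("no interaction rows found in ", path)
  idx <- which(keep)
  fields <- strsplit(lines[idx], sep, fixed = TRUE)
  bad <- which(lengths(fields) < max(columns))
  if (length(bad)) {
    stop("malformed row at line ", idx[bad[1L]], " of ", path,
         " (expected at least ", max(columns), " fields)")
  }
  from <- trimws(vapply(fields, `[[`, character(1), columns[1L]))
  to <- trimws(vapply(fields, `[[`, character(1), columns[2L]))
  empty <- which(!nzchar(from) | !nzchar(to))
  if (length(empty)) {
    stop("empty protein identifier at line ", idx[empty[1L]], " of ", path)
  }
  message(length(idx), " interaction rows read from ", path)
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# Canonical spelling of compartment labels, so that common synonyms in GO
# cellular-component exports hit the default exclusion list.
compartment_canonical <- c(
  nucleus = "nucleus", nuclear = "nucleus",
  mitochondrion = "mitochondrion", mitochondria = "mitochondrion",
  mitochondrial = "mitochondrion",
  peroxisome = "peroxisome", peroxisomes = "peroxisome",
  peroxisomal = "peroxisome"
)

normalize_compartment <- function(x) {
  x <- tolower(trimws(as.character(x)))
  hit <- match(x, names(compartment_canonical))
  ifelse(is.na(hit), x, unname(compartment_canonical[hit]))
}

#' Build the filtered operational interaction network
#'
#' Turns raw interaction pairs into the undirected, unweighted, simple,
#' connected network on which all downstream statistics are computed.
#' The cleaning order is fixed: (1) self-pairs removed and
#' duplicate/reciprocal pairs collapsed to one undirected edge; (2) proteins
#' *exclusively* annotated to excluded compartments removed (a protein is
#' removed iff it has at least one compartment annotation and every one of
#' its annotations falls in `excluded_compartments`; unannotated proteins
#' are always kept); (3) the largest connected component retained. Filtering
#' before component extraction guarantees the result is connected. When two
#' components tie for largest, the one containing the lexicographically
#' smallest protein identifier is kept, for determinism.
#'
#' @param pairs Data frame (or two-column matrix) of interaction pairs, as
#'   from [read_edge_list()].
#' @param locations Optional long-format annotation table with columns
#'   `protein` and `compartment` (one row per protein-compartment pair), as
#'   from GO cellular-component exports.
#' @param excluded_compartments Compartment labels defining the exclusive
#'   -location filter. The default removes proteins found only in the
#'   nucleus, mitochondria or peroxisomes, where interactions relevant to
#'   plasma-membrane stability cannot take place. Common synonyms
#'   (e.g. "mitochondria") are normalised automatically.
#' @param provenance Free-text tag recorded on the network (source files).
#' @return An [igraph::igraph] object: simple, undirected, connected, with
#'   vertex names carrying the protein identifiers and a `provenance` graph
#'   attribute.
#' @seealso [shortest_distances()], [write_network()]
#' @export
build_network <- function(pairs, locations = NULL,
                          excluded_compartments = c("nucleus",
                                                    "mitochondrion",
                                                    "peroxisome"),
                          provenance = "") {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) stop("no interaction pairs supplied")
  from <- as.character(pairs[[1L]])
  to <- as.character(pairs[[2L]])
  keep <- from != to
  if (!any(keep)) stop("all supplied pairs are self-interactions")
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE),
    directed = FALSE
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

  if (!is.null(locations) && length(excluded_compartments)) {
    locations <- as.data.frame(locations)
    excl <- unique(normalize_compartment(excluded_compartments))
    comp <- normalize_compartment(locations[[2L]])
    by_protein <- split(comp, as.character(locations[[1L]]))
    exclusively <- vapply(
      by_protein,
      function(cc) length(cc) > 0L && all(cc %in% excl),
      logical(1)
    )
    drop <- intersect(names(by_protein)[exclusively], igraph::V(g)$name)
    if (length(drop)) {
      message(length(drop),
              " proteins removed by the exclusive-location filter")
      g <- igraph::delete_vertices(g, drop)
    }
  }
  if (igraph::vcount(g) == 0L) {
    stop("network is empty after cleaning and location filtering")
  }

  cmp <- igraph::components(g)
  largest <- which(cmp$csize == max(cmp$csize))
  if (length(largest) > 1L) {
    smallest_member <- vapply(
      largest,
      function(ci) min(igraph::V(g)$name[cmp$membership == ci]),
      character(1)
    )
    largest <- largest[order(smallest_member)][1L]
  }
  n_drop <- igraph::vcount(g) - cmp$csize[largest]
  if (n_drop > 0L) {
    message(n_drop, " proteins outside the main component dropped")
  }
  g <- igraph::induced_subgraph(g, which(cmp$membership == largest))
  g$provenance <- provenance
  g
}

#' Shortest-path distances from an anchor protein
#'
#' Unweighted breadth-first shortest-path lengths from `anchor` to every
#' protein in the network. On a connected network (the invariant guaranteed
#' by [build_network()]) every distance is finite. The profile is the input
#' of the distance-matched random-set sampler ([sample_matched_set()]).
#'
#' @param net Interaction network (igraph).
#' @param anchor Protein identifier present in `net`.
#' @return An object of class `distance_profile`: a list with elements
#'   `anchor` and `distances` (named numeric vector, `anchor` at 0).
#' @export
shortest_distances <- function(net, anchor) {
  if (!anchor %in% igraph::V(net)$name) {
    stop("anchor '", anchor, "' is not in the network")
  }
  d <- igraph::distances(net, v = anchor)[1L, ]
  structure(list(anchor = anchor, distances = d),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat("Distance profile from anchor '", x$anchor, "' (",
      length(x$distances), " proteins)\n", sep = "")
  print(table(distance = x$distances))
  invisible(x)
}

#' Write a network as a canonical edge-list TSV
#'
#' Serialises the network as a two-column tab-separated edge list in
#' canonical form: the lexicographically smaller identifier first on each
#' row, rows sorted. Reading the file back with [read_edge_list()] +
#' [build_network()] reproduces the network bit-exactly.
#'
#' @param net Interaction network (igraph).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  o <- order(a, b, method = "radix")
  writeLines(paste(a[o], b[o], sep = "\t"), path)
  invisible(path)
}

# internal: integer adjacency index used by the statistics modules.
# Returns list(nodes = character, adj = list of integer neighbour vectors,
# n = vertex count).
adjacency_index <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  list(nodes = nodes, adj = adj, n = length(nodes))
}

# internal: map protein identifiers onto the index, dropping (with a
# message) members absent from the network. Errors if nothing maps.
map_members <- function(ai, members, label = "set") {
  members <- unique(as.character(members))
  idx <- match(members, ai$nodes)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0L) {
    message(n_drop, " of ", length(members), " members of '", label,
            "' are not in the network and were dropped")
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    stop("no members of '", label, "' map onto the network")
  }
  idx
}
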