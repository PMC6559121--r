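test_that("neighbour enrichment reproduces the worked hypergeometric example", {
  g <- enrichment_example_graph()
  expect_equal(igraph::vcount(g), 10)   # population N-1 = 9 for the test
  rec <- suppressMessages(
    neighbor_enrichment_p(g, "C", c("N1", "N2", "S3", "S4"))
  )
  expect_equal(rec$degree, 3)
  expect_equal(rec$overlap, 2)
  expect_equal(rec$p, 34 / 84, tolerance = 1e-12)
})

test_that("zero overlap gives p = 1 and a fully-matched neighbourhood the minimal p", {
  g <- enrichment_example_graph()
  rec0 <- suppressMessages(neighbor_enrichment_p(g, "C", c("F1", "F4")))
  expect_equal(rec0$overlap, 0)
  expect_equal(rec0$p, 1)

  # neighbours exactly equal to the set: p = 1 / choose(N-1, k)
  rec_min <- suppressMessages(
    neighbor_enrichment_p(g, "C", c("N1", "N2", "N3"))
  )
  expect_equal(rec_min$p, 1 / choose(9, 3), tolerance = 1e-12)
})

test_that("enrichment p equals exhaustive enumeration for small populations", {
  set.seed(17)
  for (rep in 1:40) {
    g <- rand_connected_graph(sample(6:12, 1), 0.35)
    nodes <- igraph::V(g)$name
    cand <- sample(nodes, 1)
    members <- sample(nodes, sample(2:min(5, length(nodes) - 1), 1))
    rec <- suppressMessages(neighbor_enrichment_p(g, cand, members))
    want <- oracle_hyper_upper(igraph::vcount(g) - 1,
                               rec$set_size, rec$degree, rec$overlap)
    expect_equal(rec$p, want, tolerance = 1e-12)
  }
})

test_that("p is non-increasing in overlap at fixed degree and set size", {
  n <- 40; m <- 8; k <- 6
  p <- stats::phyper(seq(0, k) - 1, m, n - 1 - m, k, lower.tail = FALSE)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("a perfect double neighbour is selected with the top rank sum", {
  # X adjacent to every member of both planted sets and nothing else
  set.seed(23)
  for (seed in 1:20) {
    gen <- generate_network(n_nodes = 150, avg_degree = 6,
                            set_sizes = c(s1 = 12, s2 = 12), seed = seed)
    g <- igraph::add_vertices(gen$network, 1, name = "X")
    g <- igraph::add_edges(g, c(rbind("X", unique(unlist(gen$sets)))))
    g <- igraph::simplify(g)
    sel <- suppressMessages(suppressWarnings(
      select_specific_neighbors(g, gen$sets)
    ))
    expect_true("X" %in% sel$selected$candidate)
    expect_equal(sel$selected$candidate[1], "X")
  }
})

test_that("the cross-interaction threshold excludes weakly attached candidates", {
  # Y has exactly 2 edges into each set: below the default threshold of 3
  g <- graph_from_edges(paste(
    "a1-a2 a2-a3 a3-a4 b1-b2 b2-b3 b3-b4 a1-b1",
    "Y-a1 Y-a2 Y-b1 Y-b2"
  ))
  sets <- list(sa = c("a1", "a2", "a3", "a4"),
               sb = c("b1", "b2", "b3", "b4"))
  sel <- suppressMessages(suppressWarnings(
    select_specific_neighbors(g, sets, top_fraction = 1)
  ))
  expect_false("Y" %in% sel$selected$candidate)
})

test_that("selection is invariant to the order sets are supplied", {
  gen <- generate_network(n_nodes = 200, set_sizes = c(u = 20, v = 20,
                                                       w = 20),
                          cross_boost = 0.03, seed = 55)
  s1 <- suppressMessages(suppressWarnings(
    select_specific_neighbors(gen$network, gen$sets)
  ))
  s2 <- suppressMessages(suppressWarnings(
    select_specific_neighbors(gen$network, rev(gen$sets))
  ))
  expect_setequal(s1$selected$candidate, s2$selected$candidate)
  m <- match(s1$selected$candidate, s2$selected$candidate)
  expect_equal(s1$selected$rank_sum, s2$selected$rank_sum[m])
})

test_that("selection count is bounded by the cross-interaction population", {
  gen <- generate_network(n_nodes = 300, set_sizes = c(a = 30, b = 30),
                          cross_boost = 0.02, seed = 77)
  sel <- suppressMessages(suppressWarnings(
    select_specific_neighbors(gen$network, gen$sets)
  ))
  rec <- sel$records
  strong <- rec[rec$overlap >= 3, ]
  eligible <- names(which(table(strong$candidate) >= 2))
  expect_true(all(sel$selected$candidate %in% eligible))
  expect_lte(nrow(sel$selected), length(eligible))
})

test_that("the rank convention flag flips the ordering direction", {
  gen <- generate_network(n_nodes = 200, set_sizes = c(a = 25, b = 25),
                          cross_boost = 0.05, seed = 91)
  hi <- suppressMessages(suppressWarnings(
    select_specific_neighbors(gen$network, gen$sets,
                              rank_direction = "high_best")
  ))
  lo <- suppressMessages(suppressWarnings(
    select_specific_neighbors(gen$network, gen$sets,
                              rank_direction = "low_best")
  ))
  expect_setequal(hi$selected$candidate, lo$selected$candidate)
  expect_true(all(diff(hi$selected$rank_sum) <= 0))
  expect_true(all(diff(lo$selected$rank_sum) >= 0))
})
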