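test_that("read_edge_list returns rows verbatim, including loops and duplicates", {
  tf <- withr::local_tempfile(lines = c("# comment", "A B", "B A", "C C"))
  suppressMessages(pairs <- read_edge_list(tf, sep = " "))
  expect_equal(pairs$from, c("A", "B", "C"))
  expect_equal(pairs$to, c("B", "A", "C"))
})

test_that("read_edge_list selects identifier columns and flags bad input", {
  tf <- withr::local_tempfile(lines = c("A\tB\t0.9"))
  suppressMessages(pairs <- read_edge_list(tf))
  expect_equal(pairs[1, ], data.frame(from = "A", to = "B"))

  bad <- withr::local_tempfile(lines = c("A\tB", "justone"))
  expect_error(suppressMessages(read_edge_list(bad)), "line 2")
  empty <- withr::local_tempfile(lines = "# only a comment")
  expect_error(read_edge_list(empty), "no interaction rows")
  expect_error(read_edge_list(tempfile()), "not found")
})

test_that("build_network dedupes, drops loops, and breaks component ties lexicographically", {
  pairs <- data.frame(from = c("A", "B", "C", "D"),
                      to = c("B", "A", "C", "E"))
  net <- build_network(pairs)
  # {A,B} and {D,E} tie at size 2; A < D so {A,B} is kept
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(igraph::ecount(net), 1)
})

test_that("exclusive-location filter removes only fully excluded, annotated proteins", {
  pairs <- data.frame(from = c("A", "B", "C", "D", "E"),
                      to = c("B", "C", "D", "E", "F"))
  loc <- data.frame(
    protein = c("F", "F", "C", "B"),
    compartment = c("nucleus", "Mitochondria", "nucleus", "cytosol")
  )
  # F: all annotations excluded (with synonym spelling) -> dropped
  # C: annotated nucleus only -> dropped; B: has a non-excluded one -> kept
  net <- suppressMessages(build_network(pairs, loc))
  expect_false(any(c("F", "C") %in% igraph::V(net)$name))
  expect_true("B" %in% igraph::V(net)$name)
  # unannotated proteins are never removed
  expect_true(all(c("A", "B") %in% igraph::V(net)$name))
})

test_that("main-component selection agrees with a union-find oracle", {
  set.seed(42)
  for (rep in 1:5) {
    nodes <- sprintf("p%03d", 1:200)
    pairs <- data.frame(from = sample(nodes[1:120], 400, replace = TRUE),
                        to = sample(nodes, 400, replace = TRUE))
    pairs <- pairs[pairs$from != pairs$to, ]
    comps <- oracle_components(pairs)
    expected <- comps[[which.max(lengths(comps))]]
    net <- suppressMessages(build_network(pairs))
    expect_setequal(igraph::V(net)$name, expected)
  }
})

test_that("build_network is idempotent and yields a simple connected graph", {
  set.seed(7)
  pairs <- data.frame(from = sample(letters, 80, replace = TRUE),
                      to = sample(letters, 80, replace = TRUE))
  net <- suppressMessages(build_network(pairs))
  expect_true(igraph::is_simple(net))
  expect_equal(igraph::components(net)$no, 1)
  el <- igraph::as_edgelist(net)
  net2 <- build_network(data.frame(from = el[, 1], to = el[, 2]))
  expect_setequal(igraph::V(net2)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(net2), igraph::ecount(net))
})

test_that("shortest_distances matches hand examples and the Floyd-Warshall oracle", {
  pg <- path_graph(c("A", "B", "C"))
  d <- shortest_distances(pg, "A")
  expect_equal(d$distances[c("A", "B", "C")], c(A = 0, B = 1, C = 2))

  star <- igraph::make_graph(c(rbind("S", paste0("L", 1:5))),
                             directed = FALSE)
  ds <- shortest_distances(star, "S")
  expect_true(all(ds$distances[paste0("L", 1:5)] == 1))
  expect_error(shortest_distances(star, "missing"), "not in the network")

  set.seed(11)
  for (rep in 1:50) {
    g <- rand_connected_graph(sample(20:60, 1), 0.08)
    anchor <- igraph::V(g)$name[1]
    got <- shortest_distances(g, anchor)$distances
    want <- oracle_fw_distances(g, anchor)
    expect_equal(got[names(want)], want)
  }
})

test_that("canonical serialisation round-trips bit-exactly", {
  set.seed(3)
  pairs <- data.frame(from = sample(LETTERS, 60, replace = TRUE),
                      to = sample(LETTERS, 60, replace = TRUE))
  net <- suppressMessages(build_network(pairs))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_network(net, f1)
  suppressMessages(
    net2 <- build_network(read_edge_list(f1))
  )
  write_network(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
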