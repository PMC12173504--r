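test_that("full-overlap construction gives exact counts, regularity and omega = 1", {
  h <- build_full_overlap(9, k_pair = 4, k_tri = 2, seed = 11)
  expect_equal(nrow(h$pair_edges), 9 * 4 / 2)   # N k_pair / 2
  expect_equal(nrow(h$triangles), 9 * 2 / 3)    # N k_tri / 3
  expect_identical(compute_overlap(h)$omega, 1)
  expect_true(all(lengths(h$pair_adj) == 4))
  expect_true(all(lengths(h$tri_of_node) == 2))

  h300 <- build_full_overlap(300, 4, 2, seed = 12)
  expect_identical(compute_overlap(h300)$omega, 1)
  # at full overlap triangle partners coincide with pairwise neighbours:
  # every node has exactly k_pair = 4 distinct co-players
  unions <- vapply(0:299, function(i) length(co_players(h300, i)$union),
                   integer(1))
  expect_true(all(unions == 4L))
  # pairwise layer equals the triangle projection
  expect_setequal(
    hypercoop:::edge_key(h300$pair_edges, 300),
    hypercoop:::edge_key(project_triangles(h300), 300))
})

test_that("construction preconditions are enforced with explicit errors", {
  expect_error(build_full_overlap(10, 4, 2), "divisible by 3")
  expect_error(build_full_overlap(9, 6, 2), "k_pair = 2 \\* k_tri")
  expect_error(build_full_overlap(6, 4, 2), "at least")
})

test_that("triangle projection enumerates de-duplicated unordered pairs", {
  h1 <- hypergraph(3, rbind(c(0, 1)), rbind(c(0, 1, 2)))
  expect_setequal(hypercoop:::edge_key(project_triangles(h1), 3),
                  hypercoop:::edge_key(rbind(c(0, 1), c(0, 2), c(1, 2)), 3))
  h0 <- hypergraph(3, rbind(c(0, 1)), NULL)
  expect_equal(nrow(project_triangles(h0)), 0)
  h2 <- hypergraph(5, rbind(c(0, 1)), rbind(c(0, 1, 2), c(2, 3, 4)))
  expect_equal(nrow(project_triangles(h2)), 6)
})

test_that("overlap counts shared edges per the definition", {
  # two of three pair edges are projections of the triangle
  h <- hypergraph(5, rbind(c(0, 1), c(1, 2), c(3, 4)), rbind(c(0, 1, 2)))
  rep1 <- compute_overlap(h)
  expect_equal(rep1$omega, 2 / 3)
  expect_equal(rep1$n_shared_edges, 2L)
  expect_equal(rep1$granularity, 1 / 3)
  # disjoint layers
  h0 <- hypergraph(6, rbind(c(0, 3), c(1, 4), c(2, 5)), rbind(c(0, 1, 2)))
  expect_equal(compute_overlap(h0)$omega, 0)
  # pure function: repeated calls agree
  expect_identical(compute_overlap(h), rep1)
  # empty pairwise layer is an error
  expect_error(compute_overlap(hypergraph(3, NULL, rbind(c(0, 1, 2)))),
               "empty")
})

test_that("criss-cross swap rewires A-B, C-D to A-D, B-C and rejects bad candidates", {
  # two isolated edges on 4 nodes (plus padding nodes for a triangle-free toy)
  h <- hypergraph(4, rbind(c(0, 1), c(2, 3)), NULL)
  h2 <- crisscross_swap(h, c(0, 1), c(2, 3))
  expect_false(is.null(h2))
  expect_setequal(hypercoop:::edge_key(h2$pair_edges, 4),
                  hypercoop:::edge_key(rbind(c(0, 3), c(1, 2)), 4))
  expect_identical(lengths(h2$pair_adj), lengths(h$pair_adj))
  expect_identical(h2$triangles, h$triangles)
  # shared endpoint (B = C)
  h3 <- hypergraph(3, rbind(c(0, 1), c(1, 2)), NULL)
  expect_null(crisscross_swap(h3, c(0, 1), c(1, 2)))
  # a link between the edge pairs (A-C exists) blocks the swap
  h4 <- hypergraph(4, rbind(c(0, 1), c(2, 3), c(0, 2)), NULL)
  expect_null(crisscross_swap(h4, c(0, 1), c(2, 3)))
  # missing edge
  expect_null(crisscross_swap(h, c(0, 2), c(1, 3)))
})

test_that("rewiring hits the target overlap, preserving degrees, triangles and connectivity", {
  h <- build_full_overlap(90, 4, 2, seed = 21)
  # already at target: returned unchanged
  expect_identical(rewire_to_overlap(h, 1.0, seed = 22), h)
  for (target in c(0.5, 0)) {
    h2 <- rewire_to_overlap(h, target, tolerance = 0.02, seed = 23)
    expect_lte(abs(compute_overlap(h2)$omega - target), 0.02)
    expect_true(all(lengths(h2$pair_adj) == 4))
    expect_identical(h2$triangles, h$triangles)
    expect_true(hypercoop:::pair_layer_connected(h2))
    expect_true(hypercoop:::tri_layer_connected(h2))
  }
  # independent connectivity oracle on the rewired pairwise layer
  h0 <- rewire_to_overlap(h, 0, tolerance = 0.02, seed = 24)
  g <- igraph::graph_from_edgelist(h0$pair_edges + 1L, directed = FALSE)
  expect_true(igraph::is_connected(g))
  # increasing the overlap is refused
  expect_error(rewire_to_overlap(h0, 0.9, seed = 25), "decreasing")
  # tolerance below granularity is refused
  expect_error(rewire_to_overlap(h, 0.5, tolerance = 1e-9), "granularity")
})

test_that("co-player sets split by layer and merge at full overlap", {
  h <- toy_simplex()
  cp <- co_players(h, 0)
  expect_identical(cp$pairwise, c(1L, 2L))
  expect_identical(cp$triangle, c(1L, 2L))
  expect_identical(cp$union, c(1L, 2L))
  # zero-overlap toy: pairwise and triangle partners are disjoint
  h0 <- hypergraph(6, rbind(c(0, 3), c(0, 4)), rbind(c(0, 1, 2)))
  cp0 <- co_players(h0, 0)
  expect_identical(cp0$pairwise, c(3L, 4L))
  expect_identical(cp0$triangle, c(1L, 2L))
  expect_identical(cp0$union, 1:4)
  # isolated node has empty sets
  expect_identical(co_players(h0, 5)$union, integer(0))
  expect_error(co_players(h0, 6), "unknown node")
})

test_that("hypergraph invariants are validated", {
  expect_error(hypergraph(3, rbind(c(0, 3)), NULL), "0 .. n_nodes")
  expect_error(hypergraph(3, rbind(c(1, 1)), NULL), "self-loops")
  expect_error(hypergraph(3, rbind(c(0, 1), c(1, 0)), NULL), "duplicate")
  expect_error(hypergraph(4, NULL, rbind(c(0, 1, 2), c(0, 2, 1))), "duplicate")
  expect_error(hypergraph(4, NULL, rbind(c(0, 1, 2), c(1, 2, 3))),
               "share more than one node")
  expect_error(hypergraph(3, NULL, rbind(c(0, 1, 1))), "distinct")
})

test_that("plain-text round-trip preserves the structure", {
  h <- build_full_overlap(30, 4, 2, seed = 31)
  path <- withr::local_tempfile(fileext = ".txt")
  write_hypergraph(h, path)
  h2 <- read_hypergraph(path)
  expect_equal(h2$n_nodes, h$n_nodes)
  expect_setequal(hypercoop:::edge_key(h2$pair_edges, 30),
                  hypercoop:::edge_key(h$pair_edges, 30))
  tri_key <- function(tr) (as.double(tr[, 1]) * 30 + tr[, 2]) * 30 + tr[, 3]
  expect_setequal(tri_key(h2$triangles), tri_key(h$triangles))
  expect_error(read_hypergraph(textConnection("E 0 1")), "header")
})

test_that("omega stays in [0, 1] on randomly built and rewired structures", {
  for (seed in 1:5) {
    h <- build_full_overlap(30, 4, 2, seed = seed)
    target <- c(0, 0.25, 0.5, 0.75, 1)[seed]
    h2 <- rewire_to_overlap(h, target, tolerance = 0.05, seed = seed + 100)
    om <- compute_overlap(h2)$omega
    expect_gte(om, 0)
    expect_lte(om, 1)
  }
})
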