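test_that("association matrices are symmetric, bipartite and zero-diagonal", {
  full <- matrix(TRUE, 96, 48)
  am <- association_matrix(full)
  expect_equal(sum(am$adjacency), 9216)  # 2 x 4608
  expect_identical(am$adjacency, t(am$adjacency))
  expect_true(all(diag(am$adjacency) == 0))
  # no input-input or hidden-hidden entries
  expect_equal(sum(am$adjacency[1:96, 1:96]), 0)
  expect_equal(sum(am$adjacency[97:144, 97:144]), 0)

  pmn <- make_architecture_mask(architecture_spec("pmn", 16, 8))
  expect_equal(sum(association_matrix(pmn)$adjacency), 128)
  expect_equal(sum(association_matrix(matrix(FALSE, 4, 2))$adjacency), 0)
  # genomes are accepted directly
  g <- init_genome(4, 2, seed = 1)
  expect_identical(association_matrix(g)$adjacency,
                   association_matrix(g$m_ih)$adjacency)
})

test_that("newman_q matches hand calculations and igraph", {
  tri2 <- two_triangle_graph()
  expect_equal(newman_q(tri2, rep(1, 6)), 0)          # single group
  expect_equal(newman_q(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # label-permutation invariance
  expect_equal(newman_q(tri2, c(2, 2, 2, 1, 1, 1)), 0.5)
  expect_equal(newman_q(matrix(0L, 5, 5), rep(1:5)), 0)  # edgeless: Q = 0

  # closed form: G equal cliques, clique partition -> Q = 1 - 1/G
  for (G in 2:4) {
    A <- clique_union(G, 4)
    labels <- rep(seq_len(G), each = 4)
    expect_equal(newman_q(A, labels), 1 - 1 / G)
  }

  # cross-check against igraph::modularity on random graphs and partitions
  set.seed(31)
  for (i in 1:10) {
    A <- random_graph(n = 9, p = 0.4, seed = 100 + i)
    if (sum(A) == 0) next
    labels <- sample.int(3, 9, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(newman_q(A, labels), igraph::modularity(g, labels))
  }
})

test_that("faction cost counts missing within-ties plus present between-ties", {
  tri2 <- two_triangle_graph()
  expect_equal(faction_cost(tri2, c(1, 1, 1, 2, 2, 2)), 0)
  expect_equal(faction_cost(tri2, rep(1, 6)), 9)   # C(6,2) - 6 edges
  # empty graph: all within pairs are missing ties
  empty <- matrix(0L, 7, 7)
  labels <- c(1, 1, 1, 2, 2, 3, 3)   # sizes 3, 2, 2
  expect_equal(faction_cost(empty, labels), 3 + 1 + 1)
  # barbell with triangle partition: only the bridge is a between tie
  expect_equal(faction_cost(barbell_graph(), c(1, 1, 1, 2, 2, 2)), 1)
})

test_that("metrics are invariant under simultaneous node permutation", {
  A <- random_graph(10, 0.35, seed = 77)
  labels <- rep(1:2, each = 5)
  set.seed(78)
  perm <- sample.int(10)
  expect_equal(faction_cost(A[perm, perm], labels[perm]),
               faction_cost(A, labels))
  expect_equal(newman_q(A[perm, perm], labels[perm]), newman_q(A, labels))
})

test_that("the exhaustive oracle solves the printed small cases", {
  expect_equal(exhaustive_faction_oracle(two_edges_graph(), 2)$faction_cost, 0)
  expect_equal(exhaustive_faction_oracle(path3_graph(), 2)$faction_cost, 1)
  o <- exhaustive_faction_oracle(two_triangle_graph(), 2)
  expect_equal(o$faction_cost, 0)
  expect_equal(o$q, 0.5)
  # the triangle partition is recovered up to label swap
  expect_equal(length(unique(o$labels[1:3])), 1)
  expect_equal(length(unique(o$labels[4:6])), 1)
  expect_true(o$labels[1] != o$labels[4])
  expect_error(exhaustive_faction_oracle(matrix(0L, 13, 13), 2), "12 nodes")
})

test_that("tabu search recovers factions and is deterministic given a seed", {
  tri2 <- two_triangle_graph()
  p <- tabu_factions(tri2, 2, tabu_params(seed = 1))
  expect_equal(p$faction_cost, 0)
  expect_equal(p$q, 0.5)
  expect_equal(length(unique(p$labels[1:3])), 1)
  expect_true(p$labels[1] != p$labels[4])
  expect_identical(tabu_factions(tri2, 2, tabu_params(seed = 9)),
                   tabu_factions(tri2, 2, tabu_params(seed = 9)))
  expect_error(tabu_factions(tri2, 1), "at least 2")
  expect_error(tabu_factions(tri2, 7), "node count")
})

test_that("tabu never does worse than random partitions of the same size", {
  A <- random_graph(12, 0.3, seed = 55)
  p <- tabu_factions(A, 3, tabu_params(seed = 2))
  set.seed(56)
  for (i in 1:50) {
    expect_lte(p$faction_cost, faction_cost(A, sample.int(3, 12, TRUE)))
  }
})

test_that("girvan-newman recovers communities on the reference graphs", {
  tri2 <- two_triangle_graph()
  p <- girvan_newman_partition(tri2)
  expect_equal(p$n_groups, 2)
  expect_equal(p$q, 0.5)

  # a single clique is one community with Q = 0
  clique <- clique_union(1, 6)
  p2 <- girvan_newman_partition(clique)
  expect_equal(p2$n_groups, 1)
  expect_equal(p2$q, 0)

  # barbell: the bridge carries the highest betweenness, so asking for two
  # groups splits at the bridge
  p3 <- girvan_newman_partition(barbell_graph(), n_groups = 2)
  expect_equal(length(unique(p3$labels[1:3])), 1)
  expect_equal(length(unique(p3$labels[4:6])), 1)
  expect_true(p3$labels[1] != p3$labels[6])

  # edgeless graph: every node its own component
  p4 <- girvan_newman_partition(matrix(0L, 4, 4))
  expect_equal(p4$n_groups, 4)
  expect_equal(p4$q, 0)
})

test_that("degree-preserving nulls preserve input degrees exactly", {
  set.seed(91)
  mask <- matrix(runif(16 * 8) < 0.4, 16, 8)
  null <- degree_preserving_null(mask, seed = 5)
  expect_identical(rowSums(null), rowSums(mask))
  expect_equal(sum(null), sum(mask))
  expect_identical(degree_preserving_null(mask, seed = 5),
                   degree_preserving_null(mask, seed = 5))
  # a full mask can only be rewired to itself
  full <- matrix(TRUE, 6, 3)
  expect_identical(degree_preserving_null(full, seed = 1), full)
})

test_that("degree-preserving nulls destroy PMN block structure", {
  pmn <- make_architecture_mask(architecture_spec("pmn", 16, 8))
  am <- association_matrix(pmn)
  q_intact <- tabu_factions(am, 2, tabu_params(seed = 1))$q
  expect_equal(q_intact, 0.5)  # two 8+4-node cliques split perfectly
  null_q <- vapply(1:100, function(s) {
    nm <- degree_preserving_null(pmn, seed = s)
    tabu_factions(association_matrix(nm), 2, tabu_params(seed = s))$q
  }, numeric(1))
  expect_lt(mean(null_q), q_intact)
})
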