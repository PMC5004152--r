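# Small graphs and genomes shared across tests. All fixtures are built in
# code; nothing is read from disk.

path3_graph <- function() {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 1] <- 1L
  A[2, 3] <- A[3, 2] <- 1L
  A
}

two_edges_graph <- function() {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- 1L
  A[3, 4] <- A[4, 3] <- 1L
  A
}

cycle_graph <- function(n = 6) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    A[i, j] <- A[j, i] <- 1L
  }
  A
}

star_graph <- function(n_leaves = 5) {
  A <- matrix(0L, n_leaves + 1L, n_leaves + 1L)
  A[1, 1 + seq_len(n_leaves)] <- 1L
  A[1 + seq_len(n_leaves), 1] <- 1L
  A
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(runif(sum(up)) < p)
  A + t(A)
}

# union of k disjoint cliques of equal size
clique_union <- function(k, size) {
  n <- k * size
  A <- matrix(0L, n, n)
  for (g in seq_len(k)) {
    idx <- (g - 1L) * size + seq_len(size)
    A[idx, idx] <- 1L
  }
  diag(A) <- 0L
  A
}

toy_genome <- function(I = 2, H = 2, seed = 1) {
  init_genome(I, H, seed = seed)
}

sigma <- function(z) 1 / (1 + exp(-z))
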