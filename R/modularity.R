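#' Symmetric association matrix of an input-to-hidden connection mask
#'
#' Represents the bipartite input-to-hidden wiring as an undirected graph on
#' `I + H` nodes: node `i <= I` is input `i`, node `I + j` is hidden node
#' `j`, and an edge joins them iff the connection is active. This is the
#' object all modularity measures operate on.
#'
#' @param mask Logical `I x H` connection mask, or a `network_genome` (its
#'   mask is used).
#' @return An `association_matrix`: list with `adjacency` (symmetric binary
#'   matrix, zero diagonal), `n_inputs`, `n_hidden` and `roles` (character
#'   vector, `"input"`/`"hidden"`).
#' @examples
#' am <- association_matrix(make_architecture_mask(
#'   architecture_spec("pmn", 16, 8)))
#' sum(am$adjacency)  # 128 = 2 * 64 active connections
#' @export
association_matrix <- function(mask) {
  if (inherits(mask, "network_genome")) mask <- mask$m_ih
  stopifnot(is.matrix(mask), is.logical(mask))
  I <- nrow(mask); H <- ncol(mask)
  n <- I + H
  adj <- matrix(0L, n, n)
  adj[seq_len(I), I + seq_len(H)] <- mask * 1L
  adj[I + seq_len(H), seq_len(I)] <- t(mask) * 1L
  structure(list(adjacency = adj, n_inputs = I, n_hidden = H,
                 roles = c(rep("input", I), rep("hidden", H))),
            class = "association_matrix")
}

as_adjacency <- function(adj) {
  if (inherits(adj, "association_matrix")) adj$adjacency
  else if (is.matrix(adj)) adj
  else stop("expected an association_matrix or adjacency matrix",
            call. = FALSE)
}

#' Newman-Girvan modularity Q of a partition
#'
#' Standard unipartite Q on the symmetrised adjacency:
#' \deqn{Q = \sum_g (e_{gg} - a_g^2)}
#' where \eqn{e_{gh}} is the fraction of edges joining groups `g` and `h` and
#' \eqn{a_g} the fraction of edge ends attached to group `g`. A graph with no
#' edges has `Q = 0` by definition here.
#'
#' @param adj An `association_matrix` (or symmetric binary adjacency matrix).
#' @param labels Integer group label per node (or a `partition`).
#' @return Q, a number in \[-1, 1\].
#' @export
newman_q <- function(adj, labels) {
  A <- as_adjacency(adj)
  labels <- partition_labels(labels, nrow(A))
  two_m <- sum(A)
  if (two_m == 0) return(0)
  groups <- sort(unique(labels))
  q <- 0
  for (g in groups) {
    in_g <- labels == g
    e_gg <- sum(A[in_g, in_g]) / two_m
    a_g <- sum(A[in_g, ]) / two_m
    q <- q + e_gg - a_g^2
  }
  q
}

partition_labels <- function(labels, n_nodes) {
  if (inherits(labels, "partition")) labels <- labels$labels
  labels <- as.integer(labels)
  if (length(labels) != n_nodes || anyNA(labels)) {
    stop("`labels` must assign every node to a group", call. = FALSE)
  }
  labels
}

#' Faction criterion cost of a partition
#'
#' Measures how far the groups are from disconnected cliques: the number of
#' missing within-group ties plus the number of present between-group ties
#' (unordered pairs, diagonal excluded). Zero for a union of disconnected
#' cliques partitioned into exactly those cliques. This is the quantity the
#' Tabu search minimises.
#'
#' @inheritParams newman_q
#' @return Integer cost.
#' @export
faction_cost <- function(adj, labels) {
  A <- as_adjacency(adj)
  labels <- partition_labels(labels, nrow(A))
  cost <- 0L
  total_edges <- sum(A) / 2
  within_edges <- 0
  within_pairs <- 0
  for (g in unique(labels)) {
    in_g <- labels == g
    s <- sum(in_g)
    within_pairs <- within_pairs + s * (s - 1) / 2
    within_edges <- within_edges + sum(A[in_g, in_g]) / 2
  }
  as.integer((within_pairs - within_edges) + (total_edges - within_edges))
}

new_partition <- function(labels, adj) {
  labels <- as.integer(labels)
  structure(
    list(labels = labels, n_groups = length(unique(labels)),
         faction_cost = faction_cost(adj, labels),
         q = newman_q(adj, labels)),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(x$labels), " nodes in ", x$n_groups,
      " groups; faction cost ", x$faction_cost, ", Q = ", signif(x$q, 4),
      "\n", sep = "")
  invisible(x)
}

#' Tabu-search parameters for faction fitting
#'
#' @param max_iterations_per_series Consecutive non-improving moves allowed
#'   before a search series stops (default 20).
#' @param tabu_tenure Number of steps a reversed move is prohibited
#'   (default 15).
#' @param random_starts Number of independently seeded initial partitions
#'   (default 3); the best result across starts is returned.
#' @param seed Integer seed; each start draws its own sub-seed.
#' @return A `tabu_params` list.
#' @export
tabu_params <- function(max_iterations_per_series = 20L, tabu_tenure = 15L,
                        random_starts = 3L, seed = 1L) {
  stopifnot(max_iterations_per_series >= 1, tabu_tenure >= 1,
            random_starts >= 1)
  structure(list(max_iterations_per_series = as.integer(max_iterations_per_series),
                 tabu_tenure = as.integer(tabu_tenure),
                 random_starts = as.integer(random_starts),
                 seed = as.integer(seed)),
            class = "tabu_params")
}

#' Fit factions by Tabu search
#'
#' Partitions the nodes into `n_groups` groups minimising the
#' [faction_cost()]. The search is a standard single-node-reassignment Tabu
#' scheme: from a random initial partition, each iteration moves the node
#' whose reassignment gives the largest cost decrease (best-improvement over
#' all node/group pairs); after a move, the reverse move is tabu for
#' `tabu_tenure` steps unless it would beat the best cost seen (aspiration).
#' A series stops after `max_iterations_per_series` consecutive
#' non-improving iterations; `random_starts` series are run from fresh seeded
#' initial partitions and the best partition found overall is returned, with
#' its faction cost and Newman Q attached.
#'
#' @param adj An `association_matrix` or symmetric binary adjacency matrix.
#' @param n_groups Number of groups (>= 2).
#' @param params A [tabu_params()].
#' @return A `partition`.
#' @examples
#' tri2 <- two_triangle_graph()
#' tabu_factions(tri2, 2, tabu_params(seed = 1))
#' @export
tabu_factions <- function(adj, n_groups, params = tabu_params()) {
  A <- as_adjacency(adj)
  n <- nrow(A)
  if (n_groups < 2) stop("`n_groups` must be at least 2", call. = FALSE)
  if (n_groups > n) {
    stop("`n_groups` (", n_groups, ") exceeds the node count (", n, ")",
         call. = FALSE)
  }
  start_seeds <- derive_seeds(params$seed, params$random_starts)
  best_labels <- NULL
  best_cost <- Inf
  for (s in seq_len(params$random_starts)) {
    res <- with_seed(start_seeds[s],
                     tabu_series(A, as.integer(n_groups), params))
    if (res$cost < best_cost) {
      best_cost <- res$cost
      best_labels <- res$labels
    }
  }
  new_partition(best_labels, A)
}

# One Tabu series from a random initial partition. Cost bookkeeping uses the
# identity cost = sum_g C(s_g, 2) - 2 * sum_g e_gg + E, so a single-node move
# v: a -> b changes cost by (s_b - s_a + 1) - 2 * (K[v, b] - K[v, a]) where
# K[v, g] counts edges from v into group g.
tabu_series <- function(A, n_groups, params) {
  n <- nrow(A)
  labels <- sample.int(n_groups, n, replace = TRUE)
  member <- outer_membership(labels, n_groups)
  K <- A %*% member
  sizes <- colSums(member)
  cur_cost <- faction_cost(A, labels)
  best_cost <- cur_cost
  best_labels <- labels
  tabu_until <- matrix(0L, n, n_groups)  # move v -> g forbidden while iter <= entry
  iter <- 0L
  stall <- 0L
  idx <- cbind(seq_len(n), labels)
  while (stall < params$max_iterations_per_series) {
    iter <- iter + 1L
    # delta matrix for all node/group moves
    k_cur <- K[idx]
    s_cur <- sizes[labels]
    delta <- sweep(-2 * K, 1, -2 * k_cur, "-")   # -2 (K[v,g] - K[v,cur])
    delta <- sweep(delta, 2, sizes, "+")          # + s_g
    delta <- delta - s_cur + 1                    # - s_cur + 1
    delta[idx] <- Inf                             # staying put is not a move
    allowed <- tabu_until < iter | (cur_cost + delta < best_cost)
    delta[!allowed] <- Inf
    pick <- arrayInd(which.min(delta), dim(delta))
    d <- delta[pick]
    if (!is.finite(d)) break
    v <- pick[1L]; to <- pick[2L]; from <- labels[v]
    # apply move
    labels[v] <- to
    idx[v, 2L] <- to
    K[, from] <- K[, from] - A[, v]
    K[, to] <- K[, to] + A[, v]
    sizes[from] <- sizes[from] - 1L
    sizes[to] <- sizes[to] + 1L
    cur_cost <- cur_cost + d
    tabu_until[v, from] <- iter + params$tabu_tenure
    if (cur_cost < best_cost) {
      best_cost <- cur_cost
      best_labels <- labels
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  list(labels = best_labels, cost = best_cost)
}

outer_membership <- function(labels, n_groups) {
  member <- matrix(0, length(labels), n_groups)
  member[cbind(seq_along(labels), labels)] <- 1
  member
}

#' Girvan-Newman community partition
#'
#' Divisive community detection by iterative removal of the highest
#' edge-betweenness edge (via igraph's edge-betweenness clustering). With
#' `n_groups` unset, the partition maximising Q along the dendrogram is
#' returned; with `n_groups` given, the dendrogram is cut at that number of
#' communities (if the graph already has more disconnected components than
#' `n_groups`, the components themselves are returned).
#'
#' @param adj An `association_matrix` or symmetric binary adjacency matrix.
#' @param n_groups Optional target number of communities.
#' @return A `partition` (with faction cost and Q attached).
#' @export
girvan_newman_partition <- function(adj, n_groups = NULL) {
  A <- as_adjacency(adj)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (igraph::ecount(g) == 0) {
    return(new_partition(seq_len(nrow(A)), A))
  }
  cm <- igraph::cluster_edge_betweenness(g)
  if (is.null(n_groups)) {
    labels <- igraph::membership(cm)
  } else {
    n_comp <- igraph::components(g)$no
    if (n_groups <= n_comp) {
      labels <- igraph::components(g)$membership
    } else {
      labels <- igraph::cut_at(cm, no = n_groups)
    }
  }
  new_partition(as.integer(labels), A)
}

#' Degree-preserving null model of a connection mask
#'
#' Randomises the wiring while preserving each input node's degree exactly:
#' an input node with `d` active connections is reassigned `d` hidden targets
#' drawn uniformly without replacement. Hidden-node degrees are not
#' constrained. This is the "no more modular than random" baseline evolved
#' masks are compared against.
#'
#' @param mask Logical `I x H` mask (or `network_genome`).
#' @param seed Integer seed.
#' @return A logical `I x H` mask with identical row sums.
#' @export
degree_preserving_null <- function(mask, seed = 1L) {
  if (inherits(mask, "network_genome")) mask <- mask$m_ih
  stopifnot(is.matrix(mask), is.logical(mask))
  H <- ncol(mask)
  degrees <- rowSums(mask)
  if (any(degrees > H)) stop("input degree exceeds hidden-layer size",
                             call. = FALSE)
  with_seed(seed, {
    out <- matrix(FALSE, nrow(mask), H)
    for (i in seq_len(nrow(mask))) {
      d <- degrees[i]
      if (d > 0) out[i, sample.int(H, d)] <- TRUE
    }
    out
  })
}

#' Exhaustive minimum-faction-cost partition (test oracle)
#'
#' Enumerates every partition of the nodes into at most `n_groups` nonempty
#' groups and returns one with minimum [faction_cost()]. Exponential in the
#' node count, so it refuses graphs with more than 12 nodes; it exists to
#' verify [tabu_factions()] on small graphs.
#'
#' @inheritParams tabu_factions
#' @return A `partition` with the global minimum faction cost.
#' @export
exhaustive_faction_oracle <- function(adj, n_groups) {
  A <- as_adjacency(adj)
  n <- nrow(A)
  if (n > 12) stop("exhaustive search is limited to 12 nodes", call. = FALSE)
  if (n_groups < 1) stop("`n_groups` must be positive", call. = FALSE)
  best_cost <- Inf
  best_labels <- rep(1L, n)
  # restricted growth strings: canonical labellings into <= n_groups blocks
  labels <- integer(n)
  recurse <- function(i, max_used) {
    if (i > n) {
      cost <- faction_cost(A, labels)
      if (cost < best_cost) {
        best_cost <<- cost
        best_labels <<- labels
      }
      return(invisible(NULL))
    }
    for (g in seq_len(min(max_used + 1L, n_groups))) {
      labels[i] <<- g
      recurse(i + 1L, max(max_used, g))
    }
  }
  labels[1] <- 1L
  recurse(2L, 1L)
  if (n == 1L) best_labels <- 1L
  new_partition(best_labels, A)
}

#' Small fixture graphs
#'
#' `two_triangle_graph()` returns the disjoint union of two triangles (six
#' nodes), the canonical perfectly-two-faction graph (faction cost 0,
#' Q = 0.5 under the triangle partition); `barbell_graph()` joins the two
#' triangles with one bridge edge.
#'
#' @return A symmetric binary adjacency matrix.
#' @export
two_triangle_graph <- function() {
  A <- matrix(0L, 6, 6)
  for (tri in list(1:3, 4:6)) {
    A[tri, tri] <- 1L
    diag(A)[tri] <- 0L
  }
  A
}

#' @rdname two_triangle_graph
#' @export
barbell_graph <- function() {
  A <- two_triangle_graph()
  A[3, 4] <- A[4, 3] <- 1L
  A
}
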