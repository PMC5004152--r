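#' Reference connective architectures
#'
#' Describes the fixed input-to-hidden wiring a network is initialised with.
#' Four kinds are supported:
#' \describe{
#'   \item{`fcnmn`}{fully connected non-modular network: every input node
#'     wired to every hidden node.}
#'   \item{`pmn`}{perfectly modular network: input block `m` (8 inputs) wired
#'     only to its own 4 hidden nodes; requires `n_inputs = 8K`,
#'     `n_hidden = 4K`.}
#'   \item{`snmn`}{sparse non-modular network: the same connection count as
#'     the equally sized PMN but placed uniformly at random (the published
#'     wiring of the original sparse benchmark is not recoverable, so this
#'     uniform stand-in is recorded in run metadata).}
#'   \item{`empty`}{no input-to-hidden connections at all; evolution must
#'     grow the network from nothing.}
#' }
#'
#' @param kind One of `"fcnmn"`, `"pmn"`, `"snmn"`, `"empty"`.
#' @param n_inputs,n_hidden Layer sizes.
#' @param n_connections Connection count for `snmn`; defaults to the PMN
#'   count `n_inputs * n_hidden / 8` when the PMN dimensions are valid.
#' @param seed Seed for `snmn` placement.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(kind = c("fcnmn", "pmn", "snmn", "empty"),
                              n_inputs, n_hidden,
                              n_connections = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_inputs >= 1, n_hidden >= 1)
  if (kind == "pmn") {
    k_in <- n_inputs / 8
    k_hid <- n_hidden / 4
    if (k_in != round(k_in) || k_hid != round(k_hid) || k_in != k_hid) {
      stop("a PMN requires n_inputs = 8K and n_hidden = 4K for the same K",
           call. = FALSE)
    }
  }
  if (kind == "snmn" && is.null(n_connections)) {
    n_connections <- as.integer(n_inputs * n_hidden / 8)
  }
  if (kind == "snmn" && n_connections > n_inputs * n_hidden) {
    stop("`n_connections` exceeds the number of possible connections",
         call. = FALSE)
  }
  structure(list(kind = kind, n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 n_connections = if (!is.null(n_connections)) as.integer(n_connections),
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

#' Build the boolean connection mask of a reference architecture
#'
#' @param arch An [architecture_spec()].
#' @return A logical `n_inputs x n_hidden` matrix; `TRUE` marks an active
#'   connection.
#' @examples
#' sum(make_architecture_mask(architecture_spec("pmn", 16, 8)))  # 64
#' @export
make_architecture_mask <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  I <- arch$n_inputs; H <- arch$n_hidden
  switch(arch$kind,
    fcnmn = matrix(TRUE, I, H),
    empty = matrix(FALSE, I, H),
    pmn = {
      m <- matrix(FALSE, I, H)
      for (mod in seq_len(I / 8L)) {
        rows <- (8L * (mod - 1L) + 1L):(8L * mod)
        cols <- (4L * (mod - 1L) + 1L):(4L * mod)
        m[rows, cols] <- TRUE
      }
      m
    },
    snmn = {
      m <- matrix(FALSE, I, H)
      idx <- with_seed(arch$seed, sample.int(I * H, arch$n_connections))
      m[idx] <- TRUE
      m
    }
  )
}

#' Initialise a network genome
#'
#' The evolving unit is a 3-layer feed-forward network with sigmoid
#' (McCulloch-Pitts) hidden and output units: input-to-hidden weights `w_ih`
#' gated by a boolean mask `m_ih`, hidden-to-output weights `w_ho` (always
#' active), hidden biases `b_h`, an output bias `b_o`, and activation
#' steepness `beta`. All weights and biases start Uniform(-3, 3); inactive
#' connections keep (and continue to mutate) their weight values, they simply
#' contribute nothing to the forward pass.
#'
#' @param n_inputs,n_hidden Layer sizes (single output node).
#' @param arch An [architecture_spec()] fixing the initial mask; defaults to
#'   a fully connected start.
#' @param seed Integer seed for the weight draw.
#' @param beta Activation steepness (default 1).
#' @return A `network_genome` object.
#' @examples
#' g <- init_genome(16, 8, seed = 1)
#' active_stats(g)
#' @export
init_genome <- function(n_inputs, n_hidden,
                        arch = architecture_spec("fcnmn", n_inputs, n_hidden),
                        seed = 1L, beta = 1) {
  stopifnot(n_inputs >= 1, n_hidden >= 1, beta > 0)
  if (arch$n_inputs != n_inputs || arch$n_hidden != n_hidden) {
    stop("architecture dimensions do not match the requested genome",
         call. = FALSE)
  }
  mask <- make_architecture_mask(arch)
  with_seed(seed, {
    w_ih <- matrix(stats::runif(n_inputs * n_hidden, -3, 3), n_inputs, n_hidden)
    w_ho <- stats::runif(n_hidden, -3, 3)
    b_h <- stats::runif(n_hidden, -3, 3)
    b_o <- stats::runif(1, -3, 3)
  })
  new_genome(w_ih, mask, w_ho, b_h, b_o, beta = beta)
}

#' Construct a network genome from its components
#'
#' Low-level constructor; validates mutual dimension consistency.
#'
#' @param w_ih Numeric `I x H` input-to-hidden weight matrix.
#' @param m_ih Logical `I x H` connection mask.
#' @param w_ho Numeric length-`H` hidden-to-output weights (always active).
#' @param b_h Numeric length-`H` hidden biases.
#' @param b_o Numeric scalar output bias.
#' @param beta Activation steepness, > 0.
#' @return A `network_genome` object.
#' @export
new_genome <- function(w_ih, m_ih, w_ho, b_h, b_o, beta = 1) {
  stopifnot(is.matrix(w_ih), is.matrix(m_ih), is.logical(m_ih),
            all(dim(w_ih) == dim(m_ih)),
            length(w_ho) == ncol(w_ih), length(b_h) == ncol(w_ih),
            length(b_o) == 1L, is.finite(b_o), beta > 0,
            all(is.finite(w_ih)))
  structure(list(w_ih = w_ih, m_ih = m_ih, w_ho = as.numeric(w_ho),
                 b_h = as.numeric(b_h), b_o = as.numeric(b_o),
                 beta = as.numeric(beta)),
            class = "network_genome")
}

#' @export
print.network_genome <- function(x, ...) {
  st <- active_stats(x)
  cat("<network_genome> ", nrow(x$w_ih), "-", ncol(x$w_ih), "-1, beta = ",
      x$beta, "\n  active connections: ", st$count, " / ",
      length(x$m_ih), " (", signif(st$fraction, 3), ")\n", sep = "")
  invisible(x)
}

#' Forward pass of a network on a pattern matrix
#'
#' Computes, for each row `x` of `patterns`,
#' `out = sigma(beta * (sum_j w_ho[j] * h_j + b_o))` with
#' `h_j = sigma(beta * (sum_i m[i,j] w[i,j] x_i + b_h[j]))` and
#' `sigma(z) = 1 / (1 + exp(-z))`. Input nodes pass their values through
#' unchanged; inactive connections contribute nothing.
#'
#' @param genome A `network_genome`.
#' @param patterns Numeric matrix, one pattern per row, `ncol == n_inputs`.
#' @return Numeric vector of outputs, one per pattern, each strictly in (0,1).
#' @export
forward <- function(genome, patterns) {
  stopifnot(inherits(genome, "network_genome"), is.matrix(patterns))
  if (ncol(patterns) != nrow(genome$w_ih)) {
    stop("pattern width (", ncol(patterns), ") does not match input count (",
         nrow(genome$w_ih), ")", call. = FALSE)
  }
  wm <- genome$w_ih * genome$m_ih
  pre_h <- patterns %*% wm
  pre_h <- pre_h + rep(genome$b_h, each = nrow(patterns))
  h <- 1 / (1 + exp(-genome$beta * pre_h))
  drop(1 / (1 + exp(-genome$beta * (h %*% genome$w_ho + genome$b_o))))
}

#' Active-connection statistics of a genome
#'
#' @param genome A `network_genome`.
#' @return A list with `count` (active input-to-hidden connections) and
#'   `fraction` (count over possible connections).
#' @export
active_stats <- function(genome) {
  stopifnot(inherits(genome, "network_genome"))
  count <- sum(genome$m_ih)
  list(count = as.integer(count), fraction = count / length(genome$m_ih))
}

#' Serialise a genome to JSON / read it back
#'
#' @param genome A `network_genome`.
#' @param path File path for the JSON document.
#' @return `write_genome` returns `path` invisibly; `read_genome` the genome.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "network_genome"))
  obj <- list(n_inputs = nrow(genome$w_ih), n_hidden = ncol(genome$w_ih),
              w_ih = genome$w_ih, m_ih = genome$m_ih * 1L,
              w_ho = genome$w_ho, b_h = genome$b_h, b_o = genome$b_o,
              beta = genome$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_genome(w_ih = obj$w_ih, m_ih = matrix(obj$m_ih == 1L, obj$n_inputs,
                                            obj$n_hidden),
             w_ho = obj$w_ho, b_h = obj$b_h, b_o = obj$b_o, beta = obj$beta)
}

#' Export a connection mask as an edge list or GraphML
#'
#' @param genome A `network_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(genome, path) {
  stopifnot(inherits(genome, "network_genome"))
  idx <- which(genome$m_ih, arr.ind = TRUE)
  df <- tibble::tibble(input_id = idx[, 1L], hidden_id = idx[, 2L])
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(genome, path) {
  stopifnot(inherits(genome, "network_genome"))
  g <- igraph::graph_from_adjacency_matrix(
    association_matrix(genome$m_ih)$adjacency, mode = "undirected")
  igraph::V(g)$role <- c(rep("input", nrow(genome$m_ih)),
                         rep("hidden", ncol(genome$m_ih)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
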