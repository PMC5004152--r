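#' Generate one block of binary input patterns
#'
#' A block is the elementary input unit of the simulations: the complete
#' enumeration of all `2^8 = 256` binary strings of length 8, presented in a
#' random row order. Each module of a network reads one such block, so an
#' input set for a `K`-module network concatenates `K` independently shuffled
#' blocks side by side.
#'
#' @param seed Integer seed controlling the row shuffle.
#' @param block_width Number of columns per block. The canonical width is 8;
#'   other widths are supported for small test cases only (the row count is
#'   always `2^block_width`).
#' @return An integer matrix with `2^block_width` rows, one per distinct
#'   binary string, in seeded random order.
#' @examples
#' b <- generate_block(seed = 1)
#' dim(b)      # 256 x 8
#' sum(b)      # 1024: half of all entries are 1
#' @export
generate_block <- function(seed, block_width = 8L) {
  stopifnot(block_width >= 1, block_width <= 16)
  n <- 2L^block_width
  # row i of the canonical table is the binary expansion of i - 1
  full <- vapply(seq_len(block_width), function(bit) {
    as.integer(bitwAnd(0:(n - 1L), bitwShiftL(1L, bit - 1L)) > 0L)
  }, integer(n))
  with_seed(seed, full[sample.int(n), , drop = FALSE])
}

#' Assemble a complete input set for one simulation replicate
#'
#' Builds the pattern matrix a network population is evaluated on:
#' `n_blocks` independently shuffled binary blocks concatenated column-wise
#' (one block per prospective module), plus a random accept subset. The task
#' of a network is to respond with output above 0.5 to the accept rows and
#' below 0.5 to all remaining rows.
#'
#' @param n_blocks Number of 8-column blocks (12 for the 96-input network).
#' @param n_accept Size of the accept subset (default 100 out of 256).
#' @param seed Integer seed; block shuffles and the accept draw are derived
#'   from it via [derive_seeds()].
#' @param block_width Columns per block (8 canonically).
#' @return An `input_set` object: a list with elements `patterns`
#'   (numeric matrix, `2^block_width` rows), `accept_rows` (integer vector),
#'   `task_kind` (`"accept_reject"`), `n_blocks`, `block_width`, `seed`.
#' @examples
#' is1 <- assemble_input_set(n_blocks = 2, n_accept = 100, seed = 7)
#' dim(is1$patterns)         # 256 x 16
#' length(is1$accept_rows)   # 100
#' @export
assemble_input_set <- function(n_blocks, n_accept = 100L, seed = 1L,
                               block_width = 8L) {
  stopifnot(n_blocks >= 1)
  n_rows <- 2L^block_width
  if (!(n_accept > 0 && n_accept < n_rows)) {
    stop("`n_accept` must lie strictly between 0 and ", n_rows,
         " (got ", n_accept, ")", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_blocks + 1L)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    generate_block(seeds[b], block_width = block_width)
  })
  patterns <- do.call(cbind, blocks)
  storage.mode(patterns) <- "double"
  accept_rows <- with_seed(seeds[n_blocks + 1L],
                           sort(sample.int(n_rows, n_accept)))
  structure(
    list(patterns = patterns, accept_rows = accept_rows,
         dull_rows = NULL, dull_intensity = NULL,
         task_kind = "accept_reject",
         n_blocks = as.integer(n_blocks), block_width = as.integer(block_width),
         seed = as.integer(seed)),
    class = "input_set"
  )
}

#' @export
print.input_set <- function(x, ...) {
  cat("<input_set> ", nrow(x$patterns), "x", ncol(x$patterns),
      " (", x$n_blocks, " blocks), task: ", x$task_kind, "\n", sep = "")
  if (x$task_kind == "accept_reject") {
    cat("  accept rows: ", length(x$accept_rows), ", reject rows: ",
        nrow(x$patterns) - length(x$accept_rows), "\n", sep = "")
  } else {
    cat("  dull rows: ", length(x$dull_rows), ", intense rows: ",
        nrow(x$patterns) - length(x$dull_rows), "\n", sep = "")
  }
  invisible(x)
}

#' Convert an input set to the dull/intense task variant
#'
#' Re-tasks an accept/reject input set as a stimulus-intensity discrimination:
#' in `n_dull` randomly chosen rows every 1 is replaced by a single per-row
#' intensity drawn from Uniform(0, 0.5) (each row gets its own value), making
#' those rows "dull"; the unmodified rows remain binary and are "intense".
#' Networks must respond with high output to dull rows and low output to
#' intense rows.
#'
#' @param base An `input_set` with binary patterns (task `accept_reject`).
#' @param n_dull Number of rows to dull (default 140 of 256).
#' @param seed Integer seed for the row draw and the intensity values.
#' @return An `input_set` with `task_kind = "dull_intense"`, `dull_rows` and
#'   per-row `dull_intensity` set; `accept_rows` is dropped.
#' @export
make_dull_variant <- function(base, n_dull = 140L, seed = 1L) {
  stopifnot(inherits(base, "input_set"))
  if (base$task_kind != "accept_reject") {
    stop("`base` must be an accept/reject input set", call. = FALSE)
  }
  if (!all(base$patterns %in% c(0, 1))) {
    stop("`base` patterns must be binary", call. = FALSE)
  }
  n_rows <- nrow(base$patterns)
  if (!(n_dull > 0 && n_dull < n_rows)) {
    stop("`n_dull` must lie strictly between 0 and ", n_rows, call. = FALSE)
  }
  out <- base
  with_seed(seed, {
    dull_rows <- sort(sample.int(n_rows, n_dull))
    intensity <- stats::runif(n_dull, 0, 0.5)
  })
  for (k in seq_along(dull_rows)) {
    r <- dull_rows[k]
    ones <- out$patterns[r, ] == 1
    out$patterns[r, ones] <- intensity[k]
  }
  out$accept_rows <- NULL
  out$dull_rows <- dull_rows
  out$dull_intensity <- intensity
  out$task_kind <- "dull_intense"
  out
}

#' Append a fresh input block to an input set
#'
#' Used by the duplication-growth experiment: when a network duplicates its
#' architecture it acquires a new input stream, realised as one freshly
#' shuffled block of all 256 binary patterns appended to the right of the
#' existing pattern matrix. The accept subset is unchanged by default, so the
#' enlarged network keeps the same target rows; set `redraw_accept = TRUE` to
#' draw a fresh accept subset of the same size instead.
#'
#' @param base An accept/reject `input_set`.
#' @param seed Integer seed for the new block shuffle (and accept redraw).
#' @param redraw_accept Redraw the accept subset? Default `FALSE`.
#' @return An `input_set` with one more block.
#' @export
extend_input_set <- function(base, seed, redraw_accept = FALSE) {
  stopifnot(inherits(base, "input_set"))
  if (base$task_kind != "accept_reject") {
    stop("only accept/reject input sets can be extended", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 2L)
  new_block <- generate_block(seeds[1L], block_width = base$block_width)
  out <- base
  out$patterns <- cbind(base$patterns, new_block)
  storage.mode(out$patterns) <- "double"
  out$n_blocks <- base$n_blocks + 1L
  if (redraw_accept) {
    out$accept_rows <- with_seed(
      seeds[2L],
      sort(sample.int(nrow(base$patterns), length(base$accept_rows)))
    )
  }
  out
}

#' Write / read an input set as CSV plus JSON sidecar
#'
#' The pattern matrix goes to `<path>.csv` (no header, one row per pattern);
#' the accept or dull designation, intensities and seeds go to `<path>.json`.
#'
#' @param x An `input_set`.
#' @param path Base path without extension.
#' @return `write_input_set` returns `path` invisibly; `read_input_set`
#'   returns the reconstructed `input_set`.
#' @export
write_input_set <- function(x, path) {
  stopifnot(inherits(x, "input_set"))
  utils::write.table(x$patterns, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(task_kind = x$task_kind, n_blocks = x$n_blocks,
               block_width = x$block_width, seed = x$seed,
               accept_rows = x$accept_rows, dull_rows = x$dull_rows,
               dull_intensity = x$dull_intensity)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_input_set
#' @export
read_input_set <- function(path) {
  patterns <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(patterns) <- NULL
  storage.mode(patterns) <- "double"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(patterns = patterns,
         accept_rows = if (length(meta$accept_rows)) as.integer(meta$accept_rows),
         dull_rows = if (length(meta$dull_rows)) as.integer(meta$dull_rows),
         dull_intensity = if (length(meta$dull_intensity)) as.numeric(meta$dull_intensity),
         task_kind = meta$task_kind,
         n_blocks = as.integer(meta$n_blocks),
         block_width = as.integer(meta$block_width),
         seed = as.integer(meta$seed)),
    class = "input_set"
  )
}
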