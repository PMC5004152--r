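#' Acceptance/rejection task fitness
#'
#' Fitness of one output vector on the accept/reject task:
#' \deqn{F = \frac{N_{>0.5}}{N_C} \cdot \frac{N_{<0.5}}{N_W}}
#' where \eqn{N_{>0.5}} is the number of accept rows answered with output
#' strictly above 0.5, \eqn{N_C} the accept-set size, \eqn{N_{<0.5}} the
#' number of remaining rows answered strictly below 0.5 and \eqn{N_W} their
#' count. The product form means some success on *both* sub-tasks is required
#' for any fitness at all; an output of exactly 0.5 is incorrect for both.
#'
#' @param outputs Numeric vector of network outputs, one per pattern row.
#' @param accept_rows Integer indices (1-based) of the accept subset.
#' @param n_patterns Total number of patterns; defaults to `length(outputs)`.
#' @return A `fitness_result` list: `fitness`, `n_correct_accept`,
#'   `n_correct_reject`, `n_accept_total`, `n_reject_total`.
#' @examples
#' out <- c(0.9, 0.9, 0.1, 0.1)
#' fitness_accept_reject(out, accept_rows = 1:2)$fitness  # 1
#' @export
fitness_accept_reject <- function(outputs, accept_rows,
                                  n_patterns = length(outputs)) {
  if (length(accept_rows) == 0L) {
    stop("`accept_rows` must not be empty", call. = FALSE)
  }
  stopifnot(length(outputs) == n_patterns,
            all(accept_rows >= 1), all(accept_rows <= n_patterns))
  two_subset_fitness(outputs, high_rows = accept_rows,
                     n_patterns = n_patterns)
}

#' Dull/intense task fitness
#'
#' Same product form as [fitness_accept_reject()], with the dull rows playing
#' the role of the high-output target set: fitness =
#' (correct dull responses / number of dull rows) * (correct intense
#' responses / number of intense rows), strict inequalities at 0.5. With the
#' canonical 256-pattern set and 140 dull rows this is
#' `(N_dull_correct/140) * (N_intense_correct/116)`.
#'
#' @param outputs Numeric vector of network outputs.
#' @param dull_rows Integer indices of the dulled rows.
#' @param n_patterns Total pattern count.
#' @return A `fitness_result`, as for [fitness_accept_reject()].
#' @export
fitness_dull <- function(outputs, dull_rows, n_patterns = length(outputs)) {
  if (length(dull_rows) == 0L) {
    stop("`dull_rows` must not be empty", call. = FALSE)
  }
  stopifnot(length(outputs) == n_patterns,
            all(dull_rows >= 1), all(dull_rows <= n_patterns))
  two_subset_fitness(outputs, high_rows = dull_rows, n_patterns = n_patterns)
}

two_subset_fitness <- function(outputs, high_rows, n_patterns) {
  is_high <- rep(FALSE, n_patterns)
  is_high[high_rows] <- TRUE
  n_c <- sum(is_high)
  n_w <- n_patterns - n_c
  n_hi <- sum(outputs[is_high] > 0.5)
  n_lo <- sum(outputs[!is_high] < 0.5)
  structure(
    list(fitness = (n_hi / n_c) * (n_lo / n_w),
         n_correct_accept = as.integer(n_hi),
         n_correct_reject = as.integer(n_lo),
         n_accept_total = as.integer(n_c),
         n_reject_total = as.integer(n_w)),
    class = "fitness_result"
  )
}

#' Evaluate the fitness of every genome in a population
#'
#' Runs [forward()] for each genome on the input set's patterns and scores the
#' outputs with the fitness function matching the input set's task.
#'
#' @param population List of `network_genome` objects, all with the same
#'   input count as the input set's pattern width.
#' @param inputs An `input_set`.
#' @return Numeric vector of fitness values, one per genome, in input order.
#' @export
evaluate_population <- function(population, inputs) {
  stopifnot(inherits(inputs, "input_set"), length(population) >= 1)
  widths <- vapply(population, function(g) nrow(g$w_ih), integer(1))
  if (any(widths != ncol(inputs$patterns))) {
    stop("all genomes must match the input-set pattern width (",
         ncol(inputs$patterns), ")", call. = FALSE)
  }
  n <- nrow(inputs$patterns)
  vapply(population, function(g) {
    out <- forward(g, inputs$patterns)
    if (inputs$task_kind == "accept_reject") {
      fitness_accept_reject(out, inputs$accept_rows, n)$fitness
    } else {
      fitness_dull(out, inputs$dull_rows, n)$fitness
    }
  }, numeric(1))
}
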