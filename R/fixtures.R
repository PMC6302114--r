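# Reference example matrices and a seeded random-matrix generator for
# tests, property suites and demonstrations.

#' Reference example state matrices
#'
#' A named collection of small state matrices spanning the interesting
#' regimes of the metric:
#' \describe{
#'   \item{`two_state_4n`}{2 states, 4 neurons; only columns 1 and 3 are
#'     extreme rays, the others are conical combinations of them.}
#'   \item{`three_state_3n`}{3 states, 3 neurons; a simplicial cone whose
#'     face lattice has 3 two-dimensional faces and 3 edges, and whose
#'     hypercube partition has 5 positive-volume regions.}
#'   \item{`worst_3state`}{3 x 4 all-zero matrix: the worst representation,
#'     `Ir = m/3 = 1`.}
#'   \item{`orthant_3n`}{3 x 3 identity: the cone is the positive orthant,
#'     covers the whole cube, `Ir = 0`.}
#' }
#'
#' @return Named list of [state_matrix()] objects.
#' @export
example_matrices <- function() {
  list(
    two_state_4n = state_matrix(rbind(c(1, 3, 1, 2),
                                      c(1, 2, 0, 1))),
    three_state_3n = state_matrix(rbind(c(2, 3, 0),
                                        c(3, 1, 0),
                                        c(1, 1, 1))),
    worst_3state = state_matrix(matrix(0, 3, 4)),
    orthant_3n = state_matrix(diag(3))
  )
}

#' Generate a random state matrix
#'
#' Entries are zero with probability `sparsity` and otherwise uniform in
#' `value_range`.  Defaults emulate a sparse population code: 30% silent
#' neuron-state pairs and activity levels up to 10 spikes per slot.
#'
#' @param m Number of input states (rows).
#' @param n Number of input neurons (columns).
#' @param sparsity Fraction of zero entries, in `[0, 1]`.
#' @param value_range Length-2 numeric, `0 <= low <= high`, for the
#'   non-zero entries.
#' @param seed Optional integer seed; identical seeds give identical
#'   matrices.
#' @return A [state_matrix()].
#' @export
random_state_matrix <- function(m, n, sparsity = 0.3,
                                value_range = c(0, 10), seed = NULL) {
  stopifnot(m >= 1, n >= 1, sparsity >= 0, sparsity <= 1,
            length(value_range) == 2)
  if (value_range[1L] < 0 || value_range[1L] > value_range[2L]) {
    stop("value_range must satisfy 0 <= low <= high", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  vals <- stats::runif(m * n, value_range[1L], value_range[2L])
  vals[stats::runif(m * n) < sparsity] <- 0
  state_matrix(matrix(vals, m, n))
}
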