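# The representation-error metric: analytic assembly of the region
# integrals, the normalization, and the grid / Monte-Carlo numerical
# evaluators based on non-negative least squares.

#' Optimal non-negative readout weights for one desired output
#'
#' Solves `min_w ||d_des - C w||^2 subject to w >= 0` (non-negative least
#' squares, Lawson-Hanson active set) for a single desired output vector.
#'
#' @param C A [state_matrix()] or non-negative numeric matrix (`m x n`).
#' @param d_des Numeric vector of length `m`: the desired output for each
#'   input state.
#' @return An object of class `weight_solution`: list with `w_hat`
#'   (non-negative `n`-vector), `d_hat` (`C %*% w_hat`) and `sq_residual`
#'   (`||d_des - d_hat||^2`).
#' @examples
#' solve_nonneg_weights(cbind(c(1, 1)), c(1, 0))  # w_hat 0.5, residual 0.5
#' @export
solve_nonneg_weights <- function(C, d_des) {
  Cm <- as.matrix(unclass(C))
  validate_state_matrix(Cm)
  d_des <- as.numeric(d_des)
  stopifnot(length(d_des) == nrow(Cm), all(is.finite(d_des)))
  nz <- colSums(abs(Cm)) > 0
  w <- numeric(ncol(Cm))
  if (any(nz)) {
    w[nz] <- pracma::lsqnonneg(Cm[, nz, drop = FALSE], d_des)$x
  }
  d_hat <- as.numeric(Cm %*% w)
  structure(list(w_hat = w, d_hat = d_hat,
                 sq_residual = sum((d_des - d_hat)^2)),
            class = "weight_solution")
}

#' @export
print.weight_solution <- function(x, ...) {
  cat("non-negative least-squares readout solution\n")
  cat("  w_hat:", paste(format(x$w_hat, digits = 6), collapse = " "), "\n")
  cat("  squared residual:", format(x$sq_residual, digits = 12), "\n")
  invisible(x)
}

# Squared Euclidean distance from each point (row of P) to the cone
# spanned by the unit rays U (columns), vectorized across points.  Exact:
# the NNLS projection has an active support of at most m linearly
# independent rays, so minimizing the restricted least-squares residual
# over all feasible ray subsets attains the optimum.
.cone_sqdist <- function(P, U, tol = 1e-9) {
  P <- as.matrix(P)
  base <- rowSums(P^2)
  r <- ncol(U)
  if (r == 0L) return(base)
  m <- ncol(P)
  best <- base                        # empty support: distance to origin
  Pt <- t(P)
  for (k in seq_len(min(m, r))) {
    subsets <- utils::combn(r, k)
    for (j in seq_len(ncol(subsets))) {
      S <- subsets[, j]
      Us <- U[, S, drop = FALSE]
      G <- crossprod(Us)
      ch <- tryCatch(chol(G), error = function(e) NULL)
      if (is.null(ch)) next          # rank-deficient subset: covered by others
      q <- crossprod(Us, Pt)         # k x npoints
      W <- backsolve(ch, forwardsolve(t(ch), q))
      feas <- colSums(W < -tol) == 0L
      if (!any(feas)) next
      r2 <- pmax(base - colSums(W * q), 0)
      upd <- feas & r2 < best
      best[upd] <- r2[upd]
    }
  }
  best
}

#' Representation error of a state matrix
#'
#' Computes `Ir(C)`, the mean squared distance from desired outputs in the
#' unit hypercube `[0, 1]^m` to the conical hull of the matrix columns,
#' i.e. the average squared error a non-negative weighted-sum readout
#' neuron commits over every possible output assignment.  Lower is better;
#' the all-zero matrix attains the maximum `m/3`.
#'
#' Three methods are available:
#' \describe{
#'   \item{`analytic`}{Face-lattice enumeration, hypercube partition and
#'     closed-form quadratic integration over each region (exact up to
#'     geometric tolerance).}
#'   \item{`grid`}{Midpoint rule: the mean squared NNLS residual over the
#'     `grid_n^m` cell midpoints `((n1, ..., nm) - 1/2) / grid_n`.}
#'   \item{`mc`}{Monte-Carlo: the mean squared NNLS residual over uniform
#'     samples, with a standard error.}
#' }
#'
#' @param C A [state_matrix()] or non-negative numeric matrix.
#' @param method One of `"analytic"`, `"grid"`, `"mc"`.
#' @param grid_n Grid resolution per dimension (midpoint rule).
#' @param samples Number of Monte-Carlo samples (>= 100).
#' @param seed Optional integer seed for the Monte-Carlo evaluator.
#' @param tol Geometric tolerance.
#' @param max_grid_points Refuse grids larger than this many midpoints.
#' @return An object of class `ir_evaluation`: list with `ir`,
#'   `ir_normalized`, `m`, `n`, `method`, `extreme_ray_columns`, and for
#'   the analytic method `per_region` (face dimension, ray set, volume and
#'   integral contribution of each region) plus `achieved_volume`; for the
#'   Monte-Carlo method also `se` (standard error) and `samples`.
#' @examples
#' representation_error(diag(3))$ir                      # 0: cone covers cube
#' representation_error(matrix(0, 3, 4))$ir              # 1 = m/3
#' @export
representation_error <- function(C, method = c("analytic", "grid", "mc"),
                                 grid_n = 16L, samples = 100000L,
                                 seed = NULL, tol = 1e-9,
                                 max_grid_points = 1e7) {
  method <- match.arg(method)
  Cm <- as.matrix(unclass(C))
  validate_state_matrix(Cm)
  m <- nrow(Cm)
  n <- ncol(Cm)
  cone <- build_cone(Cm, tol)
  res <- list(m = m, n = n, method = method,
              extreme_ray_columns = sort(cone$ray_source_columns))
  if (method == "analytic") {
    if (cone$intrinsic_dim == 0L) {
      # all-zero matrix: the only achievable output is 0, and the integral
      # of ||s||^2 over the hypercube is m/3 in closed form
      res$ir <- m / 3
      res$per_region <- data.frame(face_dim = 0L, rays = "",
                                   volume = 1, integral = m / 3)
      res$achieved_volume <- 0
    } else {
      part <- partition_cube(cone, tol)
      contrib <- vapply(part, function(reg) {
        integrate_region(reg, residual_projector(reg$face, m))
      }, numeric(1))
      res$ir <- sum(contrib)
      res$per_region <- data.frame(
        face_dim = vapply(part, function(r) r$face$dim, integer(1)),
        rays = vapply(part, function(r) {
          paste(r$face$ray_indices, collapse = ",")
        }, character(1)),
        volume = vapply(part, `[[`, numeric(1), "volume"),
        integral = contrib)
      res$achieved_volume <- achieved_output_volume(cone, part)
    }
  } else if (method == "grid") {
    grid_n <- as.integer(grid_n)
    stopifnot(grid_n >= 1L)
    if (grid_n^m > max_grid_points) {
      stop(sprintf(paste0(
        "grid of %d^%d midpoints exceeds the budget of %g points; ",
        "use method = 'mc' instead"), grid_n, m, max_grid_points),
        call. = FALSE)
    }
    mids <- (seq_len(grid_n) - 0.5) / grid_n
    P <- as.matrix(expand.grid(rep(list(mids), m)))
    res$ir <- mean(.cone_sqdist(P, cone$rays, tol))
    res$grid_n <- grid_n
  } else {
    samples <- as.integer(samples)
    stopifnot(samples >= 100L)
    if (!is.null(seed)) set.seed(seed)
    P <- matrix(stats::runif(samples * m), samples, m)
    d2 <- .cone_sqdist(P, cone$rays, tol)
    res$ir <- mean(d2)
    res$se <- stats::sd(d2) / sqrt(samples)
    res$samples <- samples
    res$seed <- seed
  }
  if (method == "mc") {
    # a Monte-Carlo estimate may exceed m/3 by sampling noise; clamp
    # without treating it as an internal inconsistency
    res$ir_normalized <- min(max(res$ir / (m / 3), 0), 1)
  } else {
    res$ir_normalized <- normalized_error(res$ir, m)
  }
  class(res) <- "ir_evaluation"
  res
}

#' Normalized representation error
#'
#' Divides `Ir(C)` by its maximum `m/3` (attained by the all-zero matrix),
#' giving a score in `[0, 1]`: 0 is the best possible representation, 1
#' the worst.  Values outside `[0, 1]` beyond tolerance indicate an
#' internal inconsistency and raise an error; values within tolerance of
#' the bounds are clamped.
#'
#' @param ir A non-negative representation error.
#' @param m Number of input states (rows of `C`).
#' @return `ir / (m / 3)`, in `[0, 1]`.
#' @export
normalized_error <- function(ir, m) {
  stopifnot(is.finite(ir), ir >= 0, m >= 1)
  irn <- ir / (m / 3)
  if (irn < -1e-9 || irn > 1 + 1e-9) {
    stop(sprintf(
      "normalized error %.12g outside [0, 1]: internal inconsistency",
      irn), call. = FALSE)
  }
  min(max(irn, 0), 1)
}

#' @export
print.ir_evaluation <- function(x, ...) {
  cat(sprintf("input-representation error (%s method)\n", x$method))
  cat(sprintf("  C: %d states x %d neurons; extreme-ray columns: %s\n",
              x$m, x$n,
              if (length(x$extreme_ray_columns)) {
                paste(x$extreme_ray_columns, collapse = ", ")
              } else "none"))
  cat(sprintf("  Ir  = %.4f   (full precision %.12g)\n", x$ir, x$ir))
  cat(sprintf("  IrN = %.4f\n", x$ir_normalized))
  if (!is.null(x$se)) {
    cat(sprintf("  Monte-Carlo SE = %.3g (%d samples)\n", x$se, x$samples))
  }
  if (!is.null(x$achieved_volume)) {
    cat(sprintf("  achieved-output volume = %.4f\n", x$achieved_volume))
  }
  invisible(x)
}

# Plain-list view of an evaluation for JSON serialization.
.evaluation_report <- function(x) {
  rep <- list(ir = x$ir, ir_normalized = x$ir_normalized, method = x$method,
              m = x$m, n = x$n, extreme_ray_columns = x$extreme_ray_columns)
  if (!is.null(x$per_region)) rep$per_region <- x$per_region
  if (!is.null(x$achieved_volume)) rep$achieved_volume <- x$achieved_volume
  if (!is.null(x$grid_n)) rep$grid_n <- x$grid_n
  if (!is.null(x$se)) {
    rep$se <- x$se
    rep$samples <- x$samples
  }
  rep
}
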