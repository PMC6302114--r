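test_that("non-negative least squares solves reference problems", {
  # achievable outputs have zero residual
  set.seed(131)
  C <- unclass(random_state_matrix(3, 4, sparsity = 0.2))
  w0 <- runif(4)
  sol <- solve_nonneg_weights(C, as.numeric(C %*% w0))
  expect_lt(sol$sq_residual, 1e-12)
  expect_true(all(sol$w_hat >= 0))
  # one neuron active in both states: best compromise is w = 0.5
  sol2 <- solve_nonneg_weights(cbind(c(1, 1)), c(1, 0))
  expect_equal(sol2$w_hat, 0.5, tolerance = 1e-9)
  expect_equal(sol2$sq_residual, 0.5, tolerance = 1e-9)
  # all-zero matrix: only the origin is achievable
  sol3 <- solve_nonneg_weights(matrix(0, 2, 3), c(0.3, 0.4))
  expect_equal(sol3$sq_residual, 0.25, tolerance = 1e-12)
  expect_equal(sol3$w_hat, rep(0, 3))
})

test_that("the vectorized cone distance equals per-point NNLS residuals", {
  set.seed(141)
  for (rep in 1:5) {
    m <- sample(2:4, 1)
    C <- unclass(random_state_matrix(m, sample(1:5, 1), sparsity = 0.3))
    U <- build_cone(C)$rays
    P <- matrix(runif(60 * m), 60, m)
    d_batch <- irmetric:::.cone_sqdist(P, U)
    d_ref <- apply(P, 1, function(p) solve_nonneg_weights(C, p)$sq_residual)
    expect_equal(d_batch, d_ref, tolerance = 1e-10)
  }
})

test_that("analytic representation error reproduces closed-form cases", {
  expect_identical(representation_error(matrix(0, 3, 4))$ir, 1)
  expect_identical(representation_error(diag(3))$ir, 0)
  # single axis ray in the square: integral of y^2
  expect_equal(representation_error(matrix(c(1, 0), 2, 1))$ir, 1 / 3,
               tolerance = 1e-12)
  # single diagonal ray: integral of (x - y)^2 / 2
  expect_equal(representation_error(matrix(c(1, 1), 2, 1))$ir, 1 / 12,
               tolerance = 1e-12)
  # 2-state example: 1/24 over the triangle above the diagonal
  expect_equal(representation_error(rbind(c(1, 3, 1, 2), c(1, 2, 0, 1)))$ir,
               1 / 24, tolerance = 1e-12)
})

test_that("analytic error equals the sum of per-region contributions", {
  set.seed(151)
  for (rep in 1:5) {
    C <- random_state_matrix(3, 4, sparsity = 0.3)
    ev <- representation_error(C)
    expect_equal(ev$ir, sum(ev$per_region$integral), tolerance = 1e-9)
    expect_equal(ev$ir_normalized, ev$ir / (3 / 3), tolerance = 1e-12)
  }
})

test_that("normalization maps the error to [0, 1] and flags inconsistencies", {
  expect_equal(normalized_error(1, 3), 1)
  expect_equal(normalized_error(0, 5), 0)
  expect_equal(normalized_error(1 / 3, 2), 0.5)
  expect_equal(normalized_error(2 / 3 + 1e-12, 2), 1)  # clamped at the bound
  expect_error(normalized_error(0.7, 2), "internal inconsistency")
})

test_that("grid evaluator implements the midpoint rule exactly", {
  expect_equal(representation_error(diag(3), method = "grid", grid_n = 7)$ir,
               0)
  # all-zero 3-state matrix: single midpoint (0.5, 0.5, 0.5)
  expect_equal(representation_error(matrix(0, 3, 1), method = "grid",
                                    grid_n = 1)$ir, 0.75)
  # N = 2: mean of ||s||^2 over the 8 midpoints with coordinates 0.25/0.75
  expect_equal(representation_error(matrix(0, 3, 1), method = "grid",
                                    grid_n = 2)$ir, 0.9375)
  expect_error(
    representation_error(matrix(0, 4, 1), method = "grid", grid_n = 100),
    "budget.*mc")
})

test_that("numerical evaluators converge to the analytic value", {
  C <- rbind(c(2, 3, 0), c(3, 1, 0), c(1, 1, 1))
  ana <- representation_error(C)$ir
  expect_lt(abs(representation_error(C, method = "grid", grid_n = 20)$ir -
                  ana), 1e-2)
  mc <- representation_error(C, method = "mc", samples = 1e5, seed = 9)
  expect_lt(abs(mc$ir - ana), 3 * mc$se)
  # reproducibility under a fixed seed
  mc2 <- representation_error(C, method = "mc", samples = 1000, seed = 4)
  mc3 <- representation_error(C, method = "mc", samples = 1000, seed = 4)
  expect_identical(mc2$ir, mc3$ir)
})

test_that("the metric is invariant to column scaling, permutations and redundancy", {
  set.seed(161)
  for (rep in 1:6) {
    m <- sample(2:4, 1)
    n <- sample(2:5, 1)
    C <- unclass(random_state_matrix(m, n, sparsity = 0.3))
    ir <- representation_error(C)$ir
    # scaling a column leaves the cone unchanged
    C_s <- C
    j <- sample(n, 1)
    C_s[, j] <- C_s[, j] * runif(1, 0.1, 10)
    expect_equal(representation_error(C_s)$ir, ir, tolerance = 1e-9)
    # column permutation
    expect_equal(representation_error(C[, sample(n), drop = FALSE])$ir, ir,
                 tolerance = 1e-9)
    # row permutation permutes the hypercube axes
    expect_equal(representation_error(C[sample(m), , drop = FALSE])$ir, ir,
                 tolerance = 1e-9)
    # appending a conical combination of existing columns
    lam <- runif(n)
    expect_equal(representation_error(cbind(C, C %*% lam))$ir, ir,
                 tolerance = 1e-9)
  }
})

test_that("appending a column never increases the error", {
  set.seed(171)
  for (rep in 1:8) {
    m <- sample(2:4, 1)
    C <- unclass(random_state_matrix(m, sample(1:4, 1), sparsity = 0.3))
    ir <- representation_error(C)$ir
    C_plus <- cbind(C, unclass(random_state_matrix(m, 1, sparsity = 0.2)))
    expect_lte(representation_error(C_plus)$ir, ir + 1e-9)
  }
})

test_that("zero error occurs exactly when all cube corners are achievable", {
  corners_resid <- function(C) {
    m <- nrow(C)
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    max(apply(corners, 1, function(s) solve_nonneg_weights(C, s)$sq_residual))
  }
  C_cover <- cbind(diag(3), c(1, 1, 1))
  expect_identical(representation_error(C_cover)$ir, 0)
  expect_lt(corners_resid(C_cover), 1e-12)
  C_partial <- rbind(c(2, 3, 0), c(3, 1, 0), c(1, 1, 1))
  expect_gt(representation_error(C_partial)$ir, 0)
  expect_gt(corners_resid(C_partial), 1e-6)
})
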