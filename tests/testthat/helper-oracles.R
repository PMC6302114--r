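# Shared oracles and generators for the test suite.

# Uniform samples inside the simplex with vertex rows V (Dirichlet(1)
# barycentric weights).
sample_simplex <- function(V, n) {
  k <- nrow(V)
  W <- matrix(stats::rexp(n * k), n, k)
  (W / rowSums(W)) %*% V
}

# Monte-Carlo oracle for the integral of t(x) Q x over the simplex with
# vertex rows V; returns estimate and standard error.
mc_simplex_quad <- function(V, Q, n = 1e5) {
  S <- sample_simplex(V, n)
  vals <- rowSums((S %*% Q) * S)
  vol <- irmetric:::.simplex_volume(V)
  c(est = vol * mean(vals), se = vol * stats::sd(vals) / sqrt(n))
}

# Squared distance from point s to the cone spanned by the columns of G
# plus the lineality space L, through non-negative least squares on
# (G, +L, -L): the independent membership oracle.
oracle_cone_sqdist <- function(s, G, L = NULL) {
  if (is.null(L) || ncol(L) == 0L) L <- matrix(0, length(s), 0L)
  A <- cbind(G, L, -L)
  if (is.null(A) || ncol(A) == 0L) return(sum(s^2))
  pracma::lsqnonneg(A, s)$resid.norm
}

# Smallest proper face of `cone` whose relative interior holds the NNLS
# projection of s onto the conical hull; returns the face record, the
# cone itself marker "inside", or "apex".
projection_face <- function(s, cone, tol = 1e-6) {
  U <- cone$rays
  w <- pracma::lsqnonneg(U, s)$x
  p <- as.numeric(U %*% w)
  if (sum((s - p)^2) < tol^2) return("inside")
  if (sum(p^2) < tol^2) return("apex")
  if (length(cone$facets) == 0L) {
    # cone spans a 1-dimensional space: the only positive-dim face is the
    # cone itself (listed as the last proper face)
    faces <- cone_proper_faces(cone)
    return(faces[[length(faces)]])
  }
  tight <- which(vapply(cone$facets, function(f) {
    abs(sum(f$normal * p)) <= tol
  }, logical(1)))
  if (length(tight) == 0L) return("inside")
  rayset <- Reduce(intersect, lapply(cone$facets[tight], `[[`, "rays"))
  for (f in cone_proper_faces(cone)) {
    if (length(f$ray_indices) == length(rayset) &&
        all(sort(f$ray_indices) == sort(rayset))) {
      return(f)
    }
  }
  stop("projection landed on an unenumerated face")
}

# Independent volume of coni(C) intersected with the unit cube: vertex
# enumeration of the hull-as-polytope (generators only, no face normals).
cone_cube_volume <- function(cone) {
  if (cone$intrinsic_dim < cone$m) return(0)
  iw <- intersect_with_cube(list(generators = cone$rays,
                                 lineality = matrix(0, cone$m, 0L)))
  simp <- irmetric:::.triangulate_polytope(iw$vertices, iw$A, iw$b)
  if (length(simp) == 0L) return(0)
  sum(vapply(simp, function(s) {
    irmetric:::.simplex_volume(iw$vertices[s, , drop = FALSE])
  }, numeric(1)))
}

# Compare two vertex sets (rows) up to ordering.
expect_same_points <- function(got, want, tol = 1e-8) {
  expect_equal(nrow(got), nrow(want))
  for (i in seq_len(nrow(want))) {
    d <- apply(got, 1L, function(v) max(abs(v - want[i, ])))
    expect_lt(min(d), tol)
  }
}
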