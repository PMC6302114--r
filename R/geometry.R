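# Low-level polyhedral primitives for small dimension (m <= ~6).
# Conventions: ray/generator sets are matrices with one generator per
# COLUMN; point sets (polytope vertices, sample points) are matrices with
# one point per ROW.  All enumeration is brute force over small subsets,
# which is exact-in-spirit and entirely adequate at the dimensions the
# metric is used for.

# Orthonormal basis of the column span of X (absolute singular-value
# threshold; inputs are unit-normalized so scale ~ 1).
.orth <- function(X, tol = 1e-9) {
  X <- as.matrix(X)
  if (ncol(X) == 0L || all(abs(X) < tol)) {
    return(matrix(0, nrow(X), 0L))
  }
  s <- svd(X)
  r <- sum(s$d > tol)
  s$u[, seq_len(r), drop = FALSE]
}

.mat_rank <- function(X, tol = 1e-9) {
  X <- as.matrix(X)
  if (ncol(X) == 0L || nrow(X) == 0L) return(0L)
  sum(svd(X)$d > tol)
}

# Orthonormal basis of the orthogonal complement of the column span of B
# within R^m.
.orth_complement <- function(B, m, tol = 1e-9) {
  if (ncol(B) == 0L) return(diag(m))
  if (ncol(B) >= m) return(matrix(0, m, 0L))
  .orth(diag(m) - B %*% t(B), tol)
}

# Greedy column de-duplication at absolute tolerance.
.dedup_cols <- function(V, tol = 1e-8) {
  k <- ncol(V)
  if (k <= 1L) return(V)
  keep <- 1L
  for (j in 2:k) {
    d <- abs(V[, keep, drop = FALSE] - V[, j])
    if (all(apply(d, 2L, max) > tol)) keep <- c(keep, j)
  }
  V[, keep, drop = FALSE]
}

# Facet enumeration for a POINTED cone of full dimension d within its own
# coordinate space.  R: d x r matrix of generators (columns).  Returns
# list(normals = d x f matrix of outward unit normals h (h . x <= 0 on the
# cone), incident = list of generator index vectors lying on each facet).
# For d == 1 the single "facet" is the apex, with empty incidence.
.cone_facets_coords <- function(R, tol = 1e-9) {
  R <- as.matrix(R)
  d <- nrow(R)
  r <- ncol(R)
  if (r == 0L) return(list(normals = matrix(0, d, 0L), incident = list()))
  if (d == 1L) {
    h <- matrix(-sign(R[1L, 1L]), 1L, 1L)
    return(list(normals = h, incident = list(integer(0))))
  }
  normals <- list()
  incident <- list()
  keys <- character(0)
  subsets <- utils::combn(r, d - 1L)
  for (j in seq_len(ncol(subsets))) {
    S <- R[, subsets[, j], drop = FALSE]
    sv <- svd(S, nu = d)
    if (sum(sv$d > tol) != d - 1L) next
    h <- sv$u[, d]
    g <- as.numeric(crossprod(h, R))
    if (max(g) <= tol) {
      # already outward
    } else if (min(g) >= -tol) {
      h <- -h
      g <- -g
    } else {
      next
    }
    inc <- which(abs(g) <= tol)
    key <- paste(inc, collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    normals[[length(normals) + 1L]] <- h
    incident[[length(incident) + 1L]] <- inc
  }
  list(normals = do.call(cbind, c(normals, list(matrix(0, d, 0L)))),
       incident = incident)
}

# Vertex enumeration for the (bounded) polyhedron {x : A x <= b} in R^m by
# inspecting all m-subsets of constraints.  Returns vertices as rows.
.polytope_vertices <- function(A, b, tol = 1e-8) {
  m <- ncol(A)
  nc <- nrow(A)
  if (nc < m) return(matrix(0, 0L, m))
  verts <- list()
  subsets <- utils::combn(nc, m)
  scale <- 1 + abs(b)
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    M <- A[idx, , drop = FALSE]
    x <- tryCatch(solve(M, b[idx]), error = function(e) NULL)
    if (is.null(x) || !all(is.finite(x))) next
    if (all(A %*% x <= b + tol * scale)) {
      verts[[length(verts) + 1L]] <- x
    }
  }
  if (length(verts) == 0L) return(matrix(0, 0L, m))
  V <- .dedup_cols(do.call(cbind, verts), tol)
  t(V)
}

# Extreme rays of the pointed full-dimensional cone {x : N x <= 0} in R^d
# (N: rows are inequality normals).  By polarity these are the facet
# normals of the cone generated by the rows of N.
.cone_rays_from_ineq <- function(N, tol = 1e-9) {
  .cone_facets_coords(t(N), tol)$normals
}

# Triangulation of a full-dimensional convex polytope given both its
# vertices and an H-representation.  P: d x k matrix of vertex coordinates
# (columns); gidx: global vertex indices carried through the recursion;
# A, b: constraints A x <= b in the current coordinates.  Returns a list of
# integer vectors of length d+1 (global indices of simplex vertices).
# Strategy: cone the first vertex over a recursive triangulation of every
# facet not containing it.
.tri_rec <- function(P, gidx, A, b, tol = 1e-8) {
  d <- nrow(P)
  k <- ncol(P)
  if (k < d + 1L) return(list())
  if (d == 1L) {
    o <- order(P[1L, ])
    if (abs(P[1L, o[k]] - P[1L, o[1L]]) <= tol) return(list())
    return(list(gidx[c(o[1L], o[k])]))
  }
  if (k == d + 1L) return(list(gidx))
  slack <- A %*% P - b            # f x k, <= 0 inside
  tight <- abs(slack) <= tol * (1 + abs(b))
  out <- list()
  seen <- character(0)
  for (j in seq_len(nrow(A))) {
    if (tight[j, 1L]) next        # facet contains the coning vertex
    W <- which(tight[j, ])
    if (length(W) < d) next
    key <- paste(W, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    PW <- P[, W, drop = FALSE]
    p0 <- PW[, 1L]
    dirs <- PW - p0
    Bf <- .orth(dirs, tol)
    if (ncol(Bf) != d - 1L) next  # not a proper facet
    Pf <- crossprod(Bf, dirs)
    Af <- A %*% Bf
    bf <- b - as.numeric(A %*% p0)
    sub <- .tri_rec(Pf, gidx[W], Af, bf, tol)
    for (s in sub) out[[length(out) + 1L]] <- c(gidx[1L], s)
  }
  out
}

# Triangulate polytope with vertices V (rows) and H-representation A, b.
# Returns list of integer vectors (rows of V) forming full-dim simplices.
.triangulate_polytope <- function(V, A, b, tol = 1e-8) {
  m <- ncol(V)
  if (nrow(V) < m + 1L) return(list())
  .tri_rec(t(V), seq_len(nrow(V)), A, b, tol)
}

# Volume of the simplex with vertices Vs (rows, d+1 x d).
.simplex_volume <- function(Vs) {
  d <- ncol(Vs)
  E <- t(Vs[-1L, , drop = FALSE]) - Vs[1L, ]
  abs(det(E)) / factorial(d)
}
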