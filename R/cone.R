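# Conical hull of the state-matrix columns: extreme rays, facets, face
# lattice, and the adjacent (projection) cone of every face.

# Preprocess columns into candidate rays: drop zero columns, normalize to
# unit length (only the direction matters for the metric), de-duplicate
# parallel columns keeping the lowest index, then strip columns that are
# conical combinations of the others (NNLS residual test).
.prepare_rays <- function(C, tol = 1e-9) {
  C <- as.matrix(unclass(C))
  norms <- sqrt(colSums(C^2))
  keep <- which(norms > tol)
  if (length(keep) == 0L) {
    return(list(rays = matrix(0, nrow(C), 0L), source = integer(0)))
  }
  U <- sweep(C[, keep, drop = FALSE], 2L, norms[keep], "/")
  src <- keep
  # de-duplicate parallel directions (1 - cosine <= tol)
  if (ncol(U) > 1L) {
    cosu <- crossprod(U)
    dup <- logical(ncol(U))
    for (j in 2:ncol(U)) {
      if (any(cosu[seq_len(j - 1L), j] >= 1 - tol & !dup[seq_len(j - 1L)])) {
        dup[j] <- TRUE
      }
    }
    U <- U[, !dup, drop = FALSE]
    src <- src[!dup]
  }
  # extremality: a ray is redundant iff it is a conical combination of the
  # remaining candidates (squared NNLS residual <= 1e-18 at unit norm)
  i <- 1L
  while (i <= ncol(U) && ncol(U) > 1L) {
    others <- U[, -i, drop = FALSE]
    res <- pracma::lsqnonneg(others, U[, i])$resid.norm
    if (res <= 1e-18) {
      U <- others
      src <- src[-i]
    } else {
      i <- i + 1L
    }
  }
  list(rays = U, source = src)
}

#' Extreme-ray columns of a state matrix
#'
#' Identifies the columns of `C` whose directions are extreme rays of the
#' conical hull of all columns: zero columns are dropped, parallel
#' duplicates keep the lowest column index, and a column is redundant when
#' it is a conical (non-negative) combination of the remaining candidates,
#' tested through its non-negative least-squares residual.
#'
#' @param C A [state_matrix()] or non-negative numeric matrix.
#' @param tol Geometric tolerance applied after unit normalization.
#' @return Sorted integer vector of column indices; empty for an all-zero
#'   matrix (degenerate cone).
#' @examples
#' extreme_ray_indices(rbind(c(1, 3, 1, 2), c(1, 2, 0, 1)))  # 1 and 3
#' @export
extreme_ray_indices <- function(C, tol = 1e-9) {
  validate_state_matrix(as.matrix(unclass(C)))
  sort(.prepare_rays(C, tol)$source)
}

#' Build the conical hull of the state-matrix columns
#'
#' Constructs the pointed cone `coni(C)` spanned by the matrix columns:
#' extreme rays (unit directions), facets of the cone within its linear
#' span (outward unit normals with ray incidences), and the full face
#' lattice.  Proper faces are enumerated as closures of intersections of
#' facet incidences; for a cone whose span is a strict subspace of `R^m`
#' the cone itself is included as a face (its points still carry a positive
#' residual in the ambient space), and the apex (dimension 0) is always
#' present.
#'
#' @inheritParams extreme_ray_indices
#' @return An object of class `input_cone` with elements `rays` (`m x r`
#'   matrix, unit columns), `ray_source_columns`, `facets` (list of
#'   `list(normal, rays)`), `faces` (list of `list(ray_indices, dim,
#'   span_basis, incident_facets)`, ordered by decreasing dimension, apex
#'   last), `intrinsic_dim`, `span_basis`, `lineality` (orthonormal basis
#'   of the orthogonal complement of the span) and `m`.
#' @examples
#' cone <- build_cone(rbind(c(2, 3, 0), c(3, 1, 0), c(1, 1, 1)))
#' length(cone_proper_faces(cone))  # 6: 3 two-dimensional faces + 3 edges
#' @export
build_cone <- function(C, tol = 1e-9) {
  validate_state_matrix(as.matrix(unclass(C)))
  m <- nrow(C)
  pr <- .prepare_rays(C, tol)
  U <- pr$rays
  r <- ncol(U)
  if (r == 0L) {
    cone <- list(rays = U, ray_source_columns = integer(0), facets = list(),
                 faces = list(.apex_face(m)), intrinsic_dim = 0L,
                 span_basis = matrix(0, m, 0L), lineality = diag(m), m = m,
                 tol = tol)
    class(cone) <- "input_cone"
    return(cone)
  }
  B <- .orth(U, tol)
  d <- ncol(B)
  Rc <- crossprod(B, U)                       # rays in span coordinates
  facets <- list()
  if (d >= 2L) {
    fc <- .cone_facets_coords(Rc, tol)
    Nm <- B %*% fc$normals
    facets <- lapply(seq_along(fc$incident), function(i) {
      list(normal = Nm[, i], rays = fc$incident[[i]])
    })
  }
  faces <- .face_lattice(U, facets, d, tol)
  if (d < m) {
    faces <- c(faces, list(list(ray_indices = seq_len(r), dim = d,
                                span_basis = B,
                                incident_facets = integer(0))))
  }
  # order by decreasing dimension, apex last
  faces <- faces[order(-vapply(faces, `[[`, numeric(1), "dim"))]
  faces <- c(faces, list(.apex_face(m)))
  cone <- list(rays = U, ray_source_columns = pr$source, facets = facets,
               faces = faces, intrinsic_dim = d, span_basis = B,
               lineality = .orth_complement(B, m, tol), m = m, tol = tol)
  class(cone) <- "input_cone"
  cone
}

.apex_face <- function(m) {
  list(ray_indices = integer(0), dim = 0L, span_basis = matrix(0, m, 0L),
       incident_facets = integer(0))
}

# Proper faces (dims 1..d-1) as closures of intersections of facet
# incidence sets; reduces to all nonempty proper ray subsets for a
# simplicial cone.
.face_lattice <- function(U, facets, d, tol) {
  r <- ncol(U)
  if (d == 1L || length(facets) == 0L) return(list())
  sets <- lapply(facets, `[[`, "rays")
  keys <- vapply(sets, paste, character(1), collapse = ",")
  repeat {
    added <- FALSE
    n0 <- length(sets)
    for (i in seq_len(n0)) {
      for (j in seq_len(n0)) {
        if (i >= j) next
        s <- intersect(sets[[i]], sets[[j]])
        if (length(s) == 0L) next
        key <- paste(s, collapse = ",")
        if (!(key %in% keys)) {
          sets[[length(sets) + 1L]] <- s
          keys <- c(keys, key)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  lapply(sets, function(s) {
    UB <- .orth(U[, s, drop = FALSE], tol)
    list(ray_indices = s, dim = ncol(UB), span_basis = UB,
         incident_facets = which(vapply(facets, function(f) {
           all(s %in% f$rays)
         }, logical(1))))
  })
}

#' Proper faces of a cone available for integration
#'
#' Returns the faces of an `input_cone` with dimension between 1 and
#' `m - 1`, i.e. the elements whose hypercube regions contribute to the
#' representation error (the apex is excluded; for a full-dimensional cone
#' the cone itself carries zero residual and is not listed).
#'
#' @param cone An `input_cone` from [build_cone()].
#' @return List of face records.
#' @export
cone_proper_faces <- function(cone) {
  Filter(function(f) f$dim >= 1L, cone$faces)
}

#' @export
print.input_cone <- function(x, ...) {
  dims <- vapply(cone_proper_faces(x), `[[`, numeric(1), "dim")
  cat(sprintf(
    "conical hull in R^%d: %d extreme ray(s) (columns %s), intrinsic dim %d\n",
    x$m, ncol(x$rays), paste(x$ray_source_columns, collapse = ", "),
    x$intrinsic_dim))
  if (length(dims)) {
    tab <- table(factor(dims, levels = sort(unique(dims), decreasing = TRUE)))
    cat("face lattice:",
        paste(sprintf("%s of dim %s", as.integer(tab), names(tab)),
              collapse = ", "), "\n")
  } else {
    cat("face lattice: no proper faces\n")
  }
  invisible(x)
}

#' Adjacent (projection) cone of a cone face
#'
#' The adjacent cone of a face is the set of points of `R^m` whose
#' Euclidean projection onto the conical hull lies on that face.  It is
#' generated by the face's rays together with the outward unit normals of
#' the facets incident to the face; when the cone does not span `R^m`, the
#' orthogonal complement of its span is attached as a lineality space
#' (projection is insensitive to those directions).  For the apex of a
#' non-degenerate cone the generators of the polar cone are returned.
#'
#' @param face A face record from [build_cone()] (an element of
#'   `cone$faces`).
#' @param cone The `input_cone` the face belongs to.
#' @return List with `generators` (`m x g` matrix, columns) and `lineality`
#'   (`m x l` orthonormal matrix, possibly zero columns).
#' @export
adjacent_cone <- function(face, cone) {
  m <- cone$m
  tol <- cone$tol
  if (face$dim == 0L) {
    if (cone$intrinsic_dim == 0L) {
      # degenerate cone: every point projects onto the apex
      return(list(generators = matrix(0, m, 0L), lineality = diag(m)))
    }
    # polar cone within the span, plus the span's complement as lineality
    Rc <- crossprod(cone$span_basis, cone$rays)
    rays_p <- .cone_rays_from_ineq(t(Rc), tol)
    return(list(generators = cone$span_basis %*% rays_p,
                lineality = cone$lineality))
  }
  gen <- cone$rays[, face$ray_indices, drop = FALSE]
  if (length(face$incident_facets)) {
    Nm <- vapply(cone$facets[face$incident_facets], `[[`, numeric(m),
                 "normal")
    gen <- cbind(gen, matrix(Nm, nrow = m))
  }
  list(generators = gen, lineality = cone$lineality)
}
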