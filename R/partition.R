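# Intersection of adjacent cones with the unit hypercube [0,1]^m: the
# bounded polytope regions over which the squared residual is integrated.

# H-representation of an adjacent cone (generators + lineality): outward
# facet normals of the pointed generator part within its own span, plus
# equality constraints confining the set to span(generators) + lineality
# when that sum is a strict subspace.
.adjacent_hrep <- function(adj, tol = 1e-9) {
  G <- adj$generators
  L <- adj$lineality
  m <- nrow(G)
  A <- matrix(0, 0L, m)
  if (ncol(G) > 0L) {
    Bg <- .orth(G, tol)
    fc <- .cone_facets_coords(crossprod(Bg, G), tol)
    if (ncol(fc$normals) > 0L) A <- t(Bg %*% fc$normals)
  }
  comp <- .orth_complement(.orth(cbind(G, L), tol), m, tol)
  if (ncol(comp) > 0L) A <- rbind(A, t(comp), -t(comp))
  A
}

#' Intersect an adjacent cone with the unit hypercube
#'
#' Enumerates the vertices of the polytope obtained by intersecting an
#' adjacent cone (from [adjacent_cone()]) with `[0, 1]^m`.  An empty or
#' measure-zero intersection yields an empty or affinely-deficient vertex
#' list, not an error.
#'
#' @param adj An adjacent cone: `list(generators, lineality)`.
#' @param tol Geometric tolerance.
#' @return List with `vertices` (`k x m` matrix, one vertex per row,
#'   de-duplicated) and the H-representation `A`, `b` of the polytope
#'   (`A x <= b`, cone inequalities followed by the `2 m` cube bounds).
#' @export
intersect_with_cube <- function(adj, tol = 1e-9) {
  m <- nrow(adj$generators)
  Ac <- .adjacent_hrep(adj, tol)
  A <- rbind(Ac, -diag(m), diag(m))
  b <- c(rep(0, nrow(Ac)), rep(0, m), rep(1, m))
  V <- .polytope_vertices(A, b, tol = 1e-8)
  list(vertices = V, A = A, b = b)
}

#' Partition the unit hypercube into integration regions
#'
#' For every cone face of dimension at least 1, intersects the face's
#' adjacent cone with `[0, 1]^m` and keeps the regions of positive volume.
#' Together with the part of the cube covered by the conical hull itself
#' (zero residual) and the measure-zero apex region, these regions tile the
#' hypercube.  For the degenerate cone of an all-zero matrix the single
#' region is the whole cube, assigned to the apex.
#'
#' @param cone An `input_cone` from [build_cone()].
#' @param tol Geometric tolerance.
#' @return An object of class `cube_partition`: a list of regions, each a
#'   list with `face`, `generators`, `lineality`, `vertices` (`k x m`,
#'   rows), `simplices` (triangulation as vertex-row indices) and `volume`.
#' @examples
#' cone <- build_cone(rbind(c(2, 3, 0), c(3, 1, 0), c(1, 1, 1)))
#' length(partition_cube(cone))  # 5 positive-volume regions
#' @export
partition_cube <- function(cone, tol = 1e-9) {
  m <- cone$m
  if (cone$intrinsic_dim == 0L) {
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    dimnames(corners) <- NULL
    A <- rbind(-diag(m), diag(m))
    b <- c(rep(0, m), rep(1, m))
    simp <- .triangulate_polytope(corners, A, b)
    reg <- list(face = cone$faces[[length(cone$faces)]],
                generators = matrix(0, m, 0L), lineality = diag(m),
                vertices = corners, simplices = simp, volume = 1)
    return(structure(list(reg), class = "cube_partition", m = m))
  }
  regions <- list()
  for (face in cone_proper_faces(cone)) {
    adj <- adjacent_cone(face, cone)
    iw <- intersect_with_cube(adj, tol)
    V <- iw$vertices
    if (nrow(V) < m + 1L) next
    simp <- .triangulate_polytope(V, iw$A, iw$b)
    if (length(simp) == 0L) next
    vol <- sum(vapply(simp, function(s) .simplex_volume(V[s, , drop = FALSE]),
                      numeric(1)))
    if (vol <= 1e-12) next
    regions[[length(regions) + 1L]] <-
      list(face = face, generators = adj$generators,
           lineality = adj$lineality, vertices = V, simplices = simp,
           volume = vol)
  }
  structure(regions, class = "cube_partition", m = m)
}

#' @export
print.cube_partition <- function(x, ...) {
  cat(sprintf("hypercube partition: %d positive-volume region(s) in [0,1]^%d\n",
              length(x), attr(x, "m")))
  for (i in seq_along(x)) {
    r <- x[[i]]
    cat(sprintf("  region %d: face dim %d (rays %s), %d vertices, volume %.6f\n",
                i, r$face$dim,
                paste(r$face$ray_indices, collapse = ","),
                nrow(r$vertices), r$volume))
  }
  invisible(x)
}

#' Volume of the achieved outputs
#'
#' The fraction of the unit hypercube covered by the conical hull itself,
#' i.e. the volume of desired outputs the readout neuron can produce with
#' zero error.  Computed as one minus the total volume of the integration
#' regions.
#'
#' @param cone An `input_cone` from [build_cone()].
#' @param partition Optionally a precomputed [partition_cube()] result.
#' @return A number in `[0, 1]`.
#' @export
achieved_output_volume <- function(cone, partition = NULL) {
  if (is.null(partition)) partition <- partition_cube(cone)
  v <- 1 - sum(vapply(partition, `[[`, numeric(1), "volume"))
  min(max(v, 0), 1)
}
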