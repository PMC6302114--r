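# Closed-form integration of the squared residual distance over the
# partition regions.  On the region of a face F the squared distance from
# s to the conical hull equals s' Q s with Q = I - P_F, P_F the orthogonal
# projector onto the linear span of F.

#' Residual quadratic form of a cone face
#'
#' For any point `s` in the face's adjacent cone, the squared Euclidean
#' distance from `s` to the conical hull equals `t(s) %*% Q %*% s` with
#' `Q = I - B B'`, `B` an orthonormal basis of the face's linear span.
#' `Q` is itself an orthogonal projector (eigenvalues 0/1): the identity
#' for the apex, zero for a face spanning all of `R^m`.
#'
#' @param face A face record from [build_cone()].
#' @param m Ambient dimension; defaults to the row count of the face's
#'   span basis.
#' @return An `m x m` symmetric projector matrix.
#' @export
residual_projector <- function(face, m = nrow(face$span_basis)) {
  B <- face$span_basis
  if (ncol(B) == 0L) return(diag(m))
  diag(m) - tcrossprod(B)
}

#' Exact integral of a quadratic form over a simplex
#'
#' Computes `integral over the simplex of t(x) Q x dx` in closed form using
#' the order-two simplex moments:
#' `Vol * (t(V) Q V + sum_i t(v_i) Q v_i) / ((d+1)(d+2))` with
#' `V = sum_i v_i`.  A degenerate simplex integrates to zero.
#'
#' @param vertices `(d+1) x d` matrix, one vertex per row, spanning a
#'   `d`-simplex.
#' @param Q A `d x d` symmetric positive-semidefinite matrix.
#' @return The value of the integral (non-negative for PSD `Q`).
#' @examples
#' integrate_quadratic_over_simplex(cbind(c(0, 1)), matrix(1))  # 1/3
#' @export
integrate_quadratic_over_simplex <- function(vertices, Q) {
  Vs <- as.matrix(vertices)
  d <- ncol(Vs)
  stopifnot(nrow(Vs) == d + 1L)
  vol <- .simplex_volume(Vs)
  if (vol == 0) return(0)
  Vsum <- colSums(Vs)
  QV <- Vs %*% Q                     # rows: Q v_i (Q symmetric)
  self_terms <- sum(QV * Vs)         # sum_i v_i' Q v_i
  cross_term <- sum(Vsum * (Q %*% Vsum))
  vol * (cross_term + self_terms) / ((d + 1) * (d + 2))
}

#' Integrate the residual form over a partition region
#'
#' Sums the closed-form simplex integrals over the region's triangulation.
#' The result does not depend on the triangulation chosen.
#'
#' @param region A region from [partition_cube()].
#' @param Q The residual projector of the region's face, from
#'   [residual_projector()].
#' @return Non-negative integral value; 0 for an empty region.
#' @export
integrate_region <- function(region, Q) {
  if (length(region$simplices) == 0L) return(0)
  sum(vapply(region$simplices, function(s) {
    integrate_quadratic_over_simplex(region$vertices[s, , drop = FALSE], Q)
  }, numeric(1)))
}
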