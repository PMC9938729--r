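#' Nested Grassmann maps
#'
#' A nested map is the pair (A, B) with A in St(m, n) and A^H B = 0 defining
#' the embedding iota_{A,B}(X) = span(A X + B) of Gr(p, m) into Gr(p, n) and
#' the corresponding projection pi_A(X) = span(A^H X).  With B = 0 the
#' embedding is isometric; a nonzero offset B lets the fitted submanifold
#' move away from the geodesic submanifolds that PGA is restricted to.
#'
#' @param A an n x m matrix with orthonormal columns.
#' @param B an n x p matrix, or NULL for a zero offset (then \code{p} must be
#'   given).  B is stored projected onto the null space of A^H; the norm of
#'   the adjustment is recorded in the \code{b_shift} diagnostic.
#' @param p subspace dimension carried by the map (required when B is NULL).
#' @return an object of class \code{"nested_map"}.
#' @export
nested_map <- function(A, B = NULL, p = NULL) {
  A <- as.matrix(A)
  check_subspace(A)
  n <- nrow(A); m <- ncol(A)
  if (m >= n) stop_dim("nested map requires m < n")
  if (is.null(B)) {
    if (is.null(p)) stop("p must be supplied when B is NULL", call. = FALSE)
    B <- matrix(if (is.complex(A)) 0 + 0i else 0, n, p)
    b_shift <- 0
  } else {
    B <- as.matrix(B)
    if (nrow(B) != n) stop_dim("B must have n rows")
    p <- ncol(B)
    Bp <- B - A %*% (ct(A) %*% B)
    b_shift <- fnorm(B - Bp)
    B <- Bp
  }
  structure(list(A = A, B = B, n = n, m = m, p = p,
                 field = field_of(A), b_shift = b_shift),
            class = "nested_map")
}

#' @export
print.nested_map <- function(x, ...) {
  cat(sprintf("Nested Grassmann map Gr(%d, %d) -> Gr(%d, %d) [%s]\n",
              x$p, x$m, x$p, x$n, x$field))
  cat(sprintf("  offset |B| = %.4g\n", fnorm(x$B)))
  invisible(x)
}

#' Natural (zero-padding) nested map
#'
#' The isometric embedding span(X) -> span([X; 0]) given by A = [I_m; 0],
#' B = 0.
#'
#' @param m,n low and high ambient dimensions, m < n.
#' @param p subspace dimension.
#' @param field \code{"real"} or \code{"complex"}.
#' @export
natural_map <- function(m, n, p, field = c("real", "complex")) {
  field <- match.arg(field)
  A <- diag(n)[, seq_len(m), drop = FALSE]
  if (field == "complex") A <- A + 0i
  nested_map(A, NULL, p = p)
}

#' Embed a subspace through a nested map
#'
#' Computes span(A X + B) in Gr(p, n) for X in Gr(p, m).
#'
#' @param map a \code{\link{nested_map}}.
#' @param X an m x p orthonormal-column matrix.
#' @export
ng_embed <- function(map, X) {
  X <- as.matrix(X)
  if (nrow(X) != map$m) stop_dim("X must live in the map's low space")
  M <- map$A %*% X + map$B[, seq_len(ncol(X)), drop = FALSE]
  orthonormalize(M)
}

#' Project a subspace through a nested map
#'
#' Computes span(A^H X) in Gr(p, m) for X in Gr(p, n).  Errors when the
#' projected matrix loses rank (the subspace is orthogonal to the projection
#' range).
#'
#' @inheritParams ng_embed
#' @param X an n x p orthonormal-column matrix.
#' @export
ng_project <- function(map, X) {
  X <- as.matrix(X)
  if (nrow(X) != map$n) stop_dim("X must live in the map's high space")
  M <- ct(map$A) %*% X
  sv <- svd(M, nu = 0, nv = 0)$d
  if (min(sv) <= 1e-12 * max(sv, 1))
    stop("subspace orthogonal to projection range", call. = FALSE)
  orthonormalize(M)
}

#' Reconstruct a subspace: embed after project
#'
#' The composite iota_{A,B}(pi_A(X)) = span(A A^H X + (I - A A^H) B); the
#' point of the embedded submanifold that represents X, whose distance to X
#' is the per-sample reconstruction error.  Idempotent.
#'
#' @inheritParams ng_project
#' @export
ng_reconstruct <- function(map, X) {
  ng_embed(map, ng_project(map, X))
}

#' Compose two nested maps
#'
#' Composition along a dimension chain: for outer (m -> n) and inner
#' (l -> m), returns the single map (l -> n) whose embedding equals
#' embedding twice.  Because A_i X + B_i has the constant Gram matrix
#' G = I + B_i^H B_i, its QR normalization is the constant upper-triangular
#' Cholesky factor of G, and the exact composite is A = A_o A_i with
#' B = A_o B_i + B_o chol(G) -- the outer offset must be rescaled by the
#' inner map's normalization.
#'
#' @param outer,inner \code{\link{nested_map}} objects with
#'   \code{inner$n == outer$m} and a common field.
#' @export
ng_compose <- function(outer, inner) {
  if (inner$n != outer$m) stop_dim("maps do not chain: inner high dim must equal outer low dim")
  if (inner$field != outer$field) stop_dim("maps are over different fields")
  if (inner$p != outer$p) stop_dim("maps carry different subspace dimensions")
  A <- outer$A %*% inner$A
  G <- diag(inner$p) + ct(inner$B) %*% inner$B
  B <- outer$A %*% inner$B + outer$B %*% chol_hermitian(G)
  nested_map(A, B)
}

#' Nested-sphere embedding (sphere special case)
#'
#' The one-step embedding of the unit sphere S^{m-1} into S^m induced by the
#' same group-augmentation construction as the nested Grassmann maps:
#' x -> R [sin(r) x; cos(r)] with r = arccos(b / sqrt(1 + b^2)), which equals
#' the Gram-Schmidt normalization of R [x; b].
#'
#' @param x a unit vector in R^m.
#' @param R an (m+1) x (m+1) orthogonal matrix.
#' @param b scalar offset.
#' @return a unit vector in R^{m+1}.
#' @export
nested_sphere_embed <- function(x, R, b) {
  x <- as.numeric(x)
  if (abs(sqrt(sum(x^2)) - 1) > 1e-8) stop("x must be a unit vector", call. = FALSE)
  r <- acos(b / sqrt(1 + b^2))
  as.numeric(R %*% c(sin(r) * x, cos(r)))
}
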