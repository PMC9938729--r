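#' Grassmann manifold geometry
#'
#' A point of the Grassmann manifold Gr(p, n) -- a p-dimensional linear
#' subspace of R^n or C^n -- is represented throughout this package by an
#' n x p matrix with orthonormal columns (a Stiefel representative).  All
#' operations are invariant to the choice of representative: two bases that
#' span the same subspace are treated as equal, and comparisons go through
#' principal angles, never through matrix entries.
#'
#' @name grassmann-geometry
NULL

#' Orthonormalize the columns of a matrix
#'
#' Returns the Gram-Schmidt orthonormal basis of the column space of
#' \code{M} (modified Gram-Schmidt with reorthogonalization), i.e. the thin
#' QR factor with real positive diagonal R.  The representative is
#' deterministic and, unlike base \code{qr()} on complex input, never
#' column-pivots -- a property the nested-map algebra relies on.
#'
#' @param M an n x p real or complex matrix of full column rank.
#' @return an n x p matrix with orthonormal columns spanning the same space.
#' @export
orthonormalize <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); p <- ncol(M)
  if (p > n) stop_dim("more columns than rows")
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[p] <= 1e-12 * sv[1]) stop("degenerate input: rank-deficient matrix", call. = FALSE)
  qr_factors(M)$Q
}

# validate a Stiefel representative
check_subspace <- function(X, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (max(Mod(ct(X) %*% X - diag(p))) > tol)
    stop("basis columns are not orthonormal", call. = FALSE)
  invisible(X)
}

check_compatible <- function(X, Y) {
  if (!all(dim(X) == dim(Y)))
    stop_dim("subspaces have mismatched dimensions")
  invisible(NULL)
}

#' Principal angles between two subspaces
#'
#' The canonical angles theta_1 <= ... <= theta_p in [0, pi/2] between
#' span(X) and span(Y), computed as arccos of the singular values of
#' X^H Y (clamped to [0, 1]).
#'
#' @param X,Y n x p orthonormal-column matrices over the same field.
#' @return numeric vector of p nondecreasing angles in radians.
#' @export
principal_angles <- function(X, Y) {
  check_compatible(X, Y)
  C <- ct(X) %*% Y
  cosv <- clamp01(svd(C, nu = 0, nv = 0)$d)   # nonincreasing
  th <- acos(cosv)                            # nondecreasing
  # arccos loses precision near zero angles; refine those from the singular
  # values of the perpendicular component, which are the sines
  small <- cosv^2 > 0.5
  if (any(small)) {
    sinv <- sort(clamp01(svd(Y - X %*% C, nu = 0, nv = 0)$d))
    th[small] <- asin(sinv[small])
  }
  th
}

#' Distances on the Grassmann manifold
#'
#' Geodesic distance \eqn{(\sum \theta_i^2)^{1/2}} under the canonical
#' invariant metric, or projection (chordal) distance
#' \eqn{(\sum \sin^2\theta_i)^{1/2} = \|P_X - P_Y\|_F/\sqrt 2}.
#'
#' @param X,Y orthonormal-column matrices representing compatible subspaces.
#' @param kind \code{"geodesic"} or \code{"projection"}.
#' @return a nonnegative scalar.
#' @export
gr_dist <- function(X, Y, kind = c("geodesic", "projection")) {
  kind <- match.arg(kind)
  th <- principal_angles(X, Y)
  if (kind == "geodesic") sqrt(sum(th^2)) else sqrt(sum(sin(th)^2))
}

#' Exponential map on the Grassmann manifold
#'
#' Follows the geodesic from span(X) with initial (horizontal) velocity H for
#' unit time: with compact SVD H = U S V^H the endpoint is
#' span(X V cos(S) + U sin(S)).
#'
#' @param X an n x p orthonormal-column matrix.
#' @param H an n x p horizontal tangent matrix (X^H H = 0).
#' @return an orthonormal-column matrix representing the endpoint.
#' @export
gr_exp <- function(X, H) {
  check_compatible(X, H)
  if (max(Mod(ct(X) %*% H)) > 1e-8)
    stop("tangent vector is not horizontal at X", call. = FALSE)
  if (fnorm(H) < 1e-15) return(X)
  s <- svd(H)
  p <- ncol(X)
  Y <- X %*% s$v %*% diag(cos(s$d), p) + s$u %*% diag(sin(s$d), p)
  orthonormalize(Y)
}

#' Logarithm map on the Grassmann manifold
#'
#' Inverse of \code{\link{gr_exp}}: the horizontal tangent vector at span(X)
#' whose geodesic reaches span(Y) at time 1.  Defined when all principal
#' angles are below pi/2 (X^H Y invertible); computed from the SVD of
#' \eqn{(I - XX^H) Y (X^H Y)^{-1}} with the arctangent of singular values.
#'
#' @param X,Y compatible orthonormal-column matrices.
#' @return an n x p horizontal tangent matrix with Frobenius norm equal to the
#'   geodesic distance.
#' @export
gr_log <- function(X, Y) {
  check_compatible(X, Y)
  M <- ct(X) %*% Y
  sv <- svd(M, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10)
    stop("cut locus: a principal angle equals pi/2", call. = FALSE)
  T0 <- (Y - X %*% M) %*% solve(M)
  s <- svd(T0)
  p <- ncol(X)
  H <- s$u %*% diag(atan(s$d), p) %*% ct(s$v)
  # re-project for exact horizontality against rounding
  H - X %*% (ct(X) %*% H)
}

#' Fréchet (Karcher) mean of subspaces
#'
#' Fixed-point iteration mu <- Exp_mu(mean of Log_mu(x_i)) for the intrinsic
#' mean under the geodesic distance, started at the first data point with unit
#' step.  Also returns the Fréchet variance, the mean squared geodesic
#' distance to the mean.
#'
#' @param data nonempty list of compatible orthonormal-column matrices.
#' @param tol convergence tolerance on the norm of the mean tangent.
#' @param max_iter maximum number of iterations.
#' @return list with components \code{mean} and \code{variance}.
#' @export
frechet_mean <- function(data, tol = 1e-9, max_iter = 200) {
  stopifnot(length(data) >= 1)
  mu <- data[[1]]
  if (length(data) == 1L) return(list(mean = mu, variance = 0))
  for (it in seq_len(max_iter)) {
    Hbar <- Reduce(`+`, lapply(data, function(X) gr_log(mu, X))) / length(data)
    if (fnorm(Hbar) <= tol) {
      v <- mean(vapply(data, function(X) gr_dist(mu, X)^2, numeric(1)))
      return(list(mean = mu, variance = v))
    }
    mu <- gr_exp(mu, Hbar)
  }
  err <- simpleError("Frechet mean did not converge")
  err$last_iterate <- mu
  stop(err)
}

#' Fréchet variance of a dataset
#'
#' Convenience wrapper returning only the variance component of
#' \code{\link{frechet_mean}}.
#' @inheritParams frechet_mean
#' @export
frechet_variance <- function(data, tol = 1e-9, max_iter = 200) {
  frechet_mean(data, tol = tol, max_iter = max_iter)$variance
}

#' Uniform random Stiefel matrix
#'
#' Draws an n x p matrix with orthonormal columns from the invariant (Haar)
#' distribution, by orthonormalizing a standard Gaussian matrix.
#'
#' @param p number of columns (p <= n).
#' @param n number of rows.
#' @param field \code{"real"} or \code{"complex"}.
#' @param seed optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @export
runif_stiefel <- function(p, n, field = c("real", "complex"), seed = NULL) {
  field <- match.arg(field)
  if (p > n) stop_dim("p must not exceed n")
  with_seed(seed, orthonormalize(rnorm_mat(n, p, field)))
}

#' Random unit horizontal tangent vector
#'
#' Projects a standard Gaussian n x p matrix onto the horizontal space at
#' span(X) via (I - X X^H) and normalizes to unit Frobenius norm, giving a
#' uniformly random direction for tangential perturbation.
#'
#' @param X an n x p orthonormal-column matrix.
#' @inheritParams runif_stiefel
#' @export
random_unit_tangent <- function(X, seed = NULL) {
  X <- as.matrix(X)
  with_seed(seed, {
    G <- rnorm_mat(nrow(X), ncol(X), field_of(X))
    H <- G - X %*% (ct(X) %*% G)
    H / fnorm(H)
  })
}

#' Orthogonal complement of a subspace
#'
#' Basis of the (n - p)-dimensional orthogonal complement of span(X) in the
#' ambient space, with a deterministic sign convention.  On Gr(p, p+1) this is
#' the diffeomorphism Gr(p, p+1) = Gr(1, p+1) used by the principal nested
#' Grassmann chain.
#'
#' @param X an n x p orthonormal-column matrix, p < n.
#' @return an n x (n - p) orthonormal-column matrix.
#' @export
gr_complement <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p >= n) stop_dim("subspace already fills the ambient space")
  Qfull <- qr.Q(qr(X), complete = TRUE)
  C <- Qfull[, (p + 1):n, drop = FALSE]
  # remove any leakage into span(X) caused by rounding, then canonicalize
  C <- C - X %*% (ct(X) %*% C)
  C <- orthonormalize(C)
  if (ncol(C) == 1L) canonical_line(C) else C
}

#' Complement swap on Gr(p, p+1)
#'
#' Maps a point of Gr(p, p+1) to the line it leaves out, realizing
#' Gr(p, p+1) = Gr(1, p+1); the inverse direction is \code{\link{gr_complement}}
#' applied to the line.
#'
#' @param X a (p+1) x p orthonormal-column matrix.
#' @export
complement_swap <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) != ncol(X) + 1L)
    stop_dim("complement swap requires ambient dimension = subspace dimension + 1")
  gr_complement(X)
}
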