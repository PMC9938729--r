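#' Unsupervised nested Grassmann reduction
#'
#' Fits the embedding parameters (A, B), A in St(m, n), A^H B = 0, that
#' minimize the mean squared reconstruction error
#' \deqn{L_u(A, B) = \frac1N \sum_i d^2(\mathrm{span}(X_i),
#'   \mathrm{span}(A A^H X_i + (I - A A^H) B))}
#' over Gr(m, n) x R^{n x p} (the loss has an O(m) symmetry in A, so only
#' span(A) matters).  Riemannian steepest descent with Barzilai-Borwein steps
#' and a monotone backtracking line search; when m > n/2 the optimization
#' variable is the (n - m)-dimensional complement of span(A), which is much
#' smaller for the one-dimension-drop fits of the principal nested Grassmann
#' chain.
#'
#' @param data list of n x p orthonormal-column matrices (points of Gr(p, n)).
#' @param m target ambient dimension, p < m < n.
#' @param distance distance driving the loss: \code{"projection"} (chordal;
#'   analytic gradient, the default for efficiency) or \code{"geodesic"}
#'   (numerical gradient).
#' @param init initialization of span(A): \code{"pca"} (top left singular
#'   vectors of the stacked bases; deterministic and exact on noiseless data),
#'   \code{"natural"} (coordinate subspace), or \code{"random"} (seeded
#'   uniform Stiefel).
#' @param max_iter,grad_tol descent iteration cap and tolerance on the
#'   Riemannian gradient norm.
#' @param seed optional integer seed (used by \code{init = "random"}).
#' @return an object of classes \code{"ng_fit"} and \code{"nested_map"}: the
#'   fitted map plus \code{loss_trace} (nonincreasing), \code{value},
#'   \code{converged}, \code{iterations} and the training data.
#' @seealso \code{\link{png_fit}} for the full chain, \code{\link{sng_fit}}
#'   for the supervised variant.
#' @export
ng_fit <- function(data, m, distance = c("projection", "geodesic"),
                   init = c("pca", "natural", "random"),
                   max_iter = 500, grad_tol = 1e-6, seed = NULL) {
  distance <- match.arg(distance)
  init <- match.arg(init)
  info <- check_dataset(data)
  n <- info$n; p <- info$p; N <- length(data)
  if (m <= p) stop_dim("target dimension m must exceed the subspace dimension p")
  if (m >= n) stop_dim("target dimension m must be below the ambient dimension n")
  field <- info$field
  use_complement <- m > n / 2
  q <- if (use_complement) n - m else m

  U0 <- init_basis(data, init, n, q, m, use_complement, field, seed)
  B0 <- matrix(if (field == "complex") 0 + 0i else 0, n, p)
  par <- list(U = U0, B = B0)

  obj <- make_unsup_objective(data, p, use_complement, distance)
  res <- riemann_gd(par, obj$loss, obj$grad, obj$retract,
                    max_iter = max_iter, grad_tol = grad_tol)
  if (!res$converged)
    warning("ng_fit: descent stopped before reaching tolerance; returning best iterate")

  U <- res$par$U; B <- res$par$B
  A <- if (use_complement) gr_complement(U) else U
  # The optimized objective reconstructs as span(A A^H X + (I - A A^H) B),
  # which embeds the un-normalized representative A^H X; ng_reconstruct()
  # embeds its QR-normalized representative.  Realign the offset to the
  # embedding convention by least squares over the per-sample R factors
  # (exact whenever the data sit on the fitted submanifold, where the R
  # factor is constant across samples).
  Bp <- B - A %*% (ct(A) %*% B)
  if (fnorm(Bp) > 1e-14) {
    Us <- lapply(data, function(X) qr_factors(ct(A) %*% X)$R)
    num <- Reduce(`+`, lapply(Us, ct))
    den <- Reduce(`+`, lapply(Us, function(Ui) Ui %*% ct(Ui)))
    B <- Bp %*% (num %*% solve(den))
  } else {
    B <- Bp
  }
  map <- nested_map(A, B)
  out <- unclass(map)
  out$loss_trace <- res$trace
  out$surrogate <- res$value
  out$value <- mean(vapply(data, function(X)
    gr_dist(X, ng_reconstruct(map, X), kind = distance)^2, numeric(1)))
  out$converged <- res$converged
  out$iterations <- res$iterations
  out$distance <- distance
  out$init <- init
  out$data <- data
  class(out) <- c("ng_fit", "nested_map")
  out
}

check_dataset <- function(data) {
  if (!is.list(data) || length(data) == 0)
    stop("data must be a nonempty list of basis matrices", call. = FALSE)
  dims <- vapply(data, function(X) dim(as.matrix(X)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_dim("all samples must share the same ambient and subspace dimensions")
  list(n = dims[1, 1], p = dims[2, 1], field = field_of(data[[1]]))
}

init_basis <- function(data, init, n, q, m, use_complement, field, seed) {
  if (init == "random") {
    return(runif_stiefel(q, n, field, seed = seed))
  }
  if (init == "natural") {
    E <- diag(n)
    if (field == "complex") E <- E + 0i
    cols <- if (use_complement) (m + 1):n else seq_len(m)
    return(E[, cols, drop = FALSE])
  }
  # pca: left singular vectors of the horizontally stacked representatives
  stack <- do.call(cbind, data)
  u <- svd(stack)$u
  if (ncol(u) < n) {         # complete the basis when N * p < n
    u <- cbind(u, gr_complement(u))
  }
  cols <- if (use_complement) (m + 1):n else seq_len(m)
  orthonormalize(u[, cols, drop = FALSE])
}

# objective closures for the unsupervised loss under either parameterization
make_unsup_objective <- function(data, p, use_complement, distance) {
  N <- length(data)
  recon <- function(par, X) {
    if (use_complement) {
      Q <- par$U
      X - Q %*% (ct(Q) %*% (X - par$B))
    } else {
      A <- par$U
      A %*% (ct(A) %*% (X - par$B)) + par$B
    }
  }
  if (distance == "projection") {
    loss <- function(par) {
      s <- 0
      for (X in data) {
        M <- recon(par, X)
        G <- solve(ct(M) %*% M)
        S <- ct(X) %*% M
        s <- s + (p - Re(sum(diag(S %*% G %*% ct(S)))))
      }
      s / N
    }
    grad <- function(par) {
      U <- par$U
      gU <- U * 0; gB <- par$B * 0
      for (X in data) {
        C <- X - par$B
        M <- recon(par, X)
        G <- solve(ct(M) %*% M)
        S <- ct(X) %*% M
        SG <- S %*% G
        W <- X %*% SG - M %*% (G %*% (ct(S) %*% SG))
        if (use_complement) {
          gU <- gU + (2 / N) * (W %*% (ct(C) %*% U) + C %*% (ct(W) %*% U))
          gB <- gB - (2 / N) * (U %*% (ct(U) %*% W))
        } else {
          K <- ct(U) %*% C
          gU <- gU - (2 / N) * (W %*% ct(K) + C %*% (ct(W) %*% U))
          gB <- gB - (2 / N) * (W - U %*% (ct(U) %*% W))
        }
      }
      list(U = gU - U %*% (ct(U) %*% gU), B = gB)
    }
  } else {
    loss <- function(par) {
      s <- 0
      for (X in data) {
        M <- recon(par, X)
        s <- s + gr_dist(X, orthonormalize(M), kind = "geodesic")^2
      }
      s / N
    }
    grad <- function(par) {
      g <- num_grad(par, loss)
      U <- par$U
      list(U = g$U - U %*% (ct(U) %*% g$U), B = g$B)
    }
  }
  retract <- function(par) {
    par$U <- orthonormalize(par$U)
    par
  }
  list(loss = loss, grad = grad, retract = retract)
}

#' Unsupervised reconstruction loss
#'
#' The objective minimized by \code{\link{ng_fit}}: the mean squared distance
#' between each sample and span(A A^H X_i + (I - A A^H) B).  This form is
#' invariant under A -> A O for orthogonal/unitary O, so only span(A)
#' matters.  (It embeds the un-normalized projected representative; the
#' fitted model's reported \code{value} is the reconstruction error through
#' \code{\link{ng_reconstruct}} after the offset realignment.)
#'
#' @param A n x m orthonormal-column matrix.
#' @param B n x p offset matrix (projected internally onto the null space of
#'   A^H).
#' @param data list of n x p orthonormal-column matrices.
#' @param distance \code{"projection"} or \code{"geodesic"}.
#' @export
ng_loss <- function(A, B, data, distance = c("projection", "geodesic")) {
  distance <- match.arg(distance)
  A <- as.matrix(A); B <- as.matrix(B)
  Bp <- B - A %*% (ct(A) %*% B)
  mean(vapply(data, function(X) {
    M <- A %*% (ct(A) %*% X) + Bp
    gr_dist(X, orthonormalize(M), kind = distance)^2
  }, numeric(1)))
}

#' @export
print.ng_fit <- function(x, ...) {
  cat(sprintf("Nested Grassmann reduction Gr(%d, %d) -> Gr(%d, %d) [%s]\n",
              x$p, x$n, x$p, x$m, x$field))
  cat(sprintf("  %s distance, %d iterations, final loss %.6g%s\n",
              x$distance, x$iterations, x$value,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
predict.ng_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  lapply(newdata, function(X) ng_project(object, X))
}

#' @export
fitted.ng_fit <- function(object, ...) {
  lapply(object$data, function(X) ng_reconstruct(object, X))
}

#' @export
residuals.ng_fit <- function(object, distance = c("geodesic", "projection"), ...) {
  distance <- match.arg(distance)
  vapply(object$data, function(X)
    gr_dist(X, ng_reconstruct(object, X), kind = distance), numeric(1))
}

#' Ratio of expressed variance after projection
#'
#' Fréchet variance (always under the geodesic distance, so that nested
#' Grassmann fits and PGA are compared on one scale) of the data projected
#' onto the fitted submanifold -- the reconstructions, measured in the
#' original space -- divided by the Fréchet variance of the original data.
#' Data lying exactly on the submanifold therefore express all of their
#' variance regardless of the offset B.
#'
#' @param object a fitted \code{\link{ng_fit}} / \code{\link{sng_fit}} map or
#'   a \code{\link{png_fit}} model.
#' @param data dataset in the original space; defaults to the training data.
#' @param ... unused.
#' @return for a single map, a scalar ratio; for a \code{png_fit} model, a
#'   data frame with one row per level of the chain.
#' @export
explained_variance <- function(object, data = NULL, ...) {
  UseMethod("explained_variance")
}

#' @export
explained_variance.nested_map <- function(object, data = NULL, ...) {
  if (is.null(data)) data <- object$data
  if (is.null(data)) stop("data required", call. = FALSE)
  v0 <- frechet_variance(data)
  if (v0 < 1e-14) stop("degenerate dataset: zero variance", call. = FALSE)
  v1 <- frechet_variance(lapply(data, function(X) ng_reconstruct(object, X)))
  min(v1 / v0, 1)
}
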