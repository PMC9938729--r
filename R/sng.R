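#' Neighbor affinity for supervised reduction
#'
#' Builds the N x N affinity a = g_w - g_b from class labels: g_w(i, j) = 1
#' when i is among the nu_w same-class nearest neighbors of j or vice versa;
#' g_b(i, j) = 1 when i is among the nu_b different-class nearest neighbors
#' of j or vice versa.  Neighbors are ranked by geodesic distance, ties
#' broken by smallest sample index.  Entries lie in {-1, 0, 1} (the two
#' graphs involve disjoint label pairs), the matrix is symmetric with zero
#' diagonal.
#'
#' @param data list of orthonormal-column matrices.
#' @param labels integer class labels, one per sample.
#' @param nu_w within-class neighbor count; default min(5, smallest class - 1).
#' @param nu_b between-class neighbor count, default 5 (capped at the number
#'   of available different-class samples).
#' @return matrix of class \code{"ng_affinity"}.
#' @export
ng_affinity <- function(data, labels, nu_w = NULL, nu_b = 5) {
  N <- length(data)
  if (length(labels) != N) stop_dim("one label per sample required")
  if (N < 2) stop_dim("at least two samples required")
  labels <- as.integer(factor(labels))
  sizes <- table(labels)
  if (is.null(nu_w)) nu_w <- max(1L, min(5L, min(sizes) - 1L))
  nu_w <- as.integer(nu_w); nu_b <- as.integer(nu_b)
  if (nu_w < 1 || nu_b < 1) stop("neighbor counts must be >= 1", call. = FALSE)
  bad <- names(sizes)[sizes <= nu_w]
  if (length(bad))
    stop(sprintf("class %s has too few samples for nu_w = %d",
                 paste(bad, collapse = ", "), nu_w), call. = FALSE)
  # with a single class there are no between-class pairs and g_b is empty
  if (length(sizes) > 1) nu_b <- min(nu_b, N - max(sizes))

  D <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    D[i, j] <- D[j, i] <- gr_dist(data[[i]], data[[j]], "geodesic")
  }
  gw <- matrix(0L, N, N); gb <- matrix(0L, N, N)
  for (i in seq_len(N)) {
    same <- setdiff(which(labels == labels[i]), i)
    diff <- which(labels != labels[i])
    nw <- same[order(D[i, same], same)][seq_len(min(nu_w, length(same)))]
    nb <- diff[order(D[i, diff], diff)][seq_len(min(nu_b, length(diff)))]
    gw[i, nw] <- 1L
    gb[i, nb] <- 1L
  }
  gw <- pmax(gw, t(gw))
  gb <- pmax(gb, t(gb))
  a <- gw - gb
  structure(a, class = c("ng_affinity", "matrix"),
            nu_w = nu_w, nu_b = nu_b)
}

#' Supervised nested Grassmann loss
#'
#' The affinity-weighted sum of squared distances between projected samples,
#' \deqn{L_s(A) = \frac1{N^2} \sum_{i,j} a(X_i, X_j)\,
#'   d^2(\mathrm{span}(A^H X_i), \mathrm{span}(A^H X_j)),}
#' negative-leaning values indicating that same-class points are close and
#' different-class points far after projection.  Invariant under A -> A O.
#'
#' @param A n x m orthonormal-column matrix.
#' @param data list of n x p orthonormal-column matrices.
#' @param affinity an \code{\link{ng_affinity}} matrix (or any symmetric
#'   matrix of weights).
#' @param distance \code{"projection"} or \code{"geodesic"}.
#' @export
sng_loss <- function(A, data, affinity,
                     distance = c("projection", "geodesic")) {
  distance <- match.arg(distance)
  N <- length(data)
  proj <- lapply(data, function(X) {
    M <- ct(A) %*% X
    sv <- svd(M, nu = 0, nv = 0)$d
    if (min(sv) <= 1e-12 * max(sv, 1))
      stop("projection collapses a sample to lower rank", call. = FALSE)
    orthonormalize(M)
  })
  s <- 0
  idx <- which(affinity != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    s <- s + 2 * affinity[i, j] * gr_dist(proj[[i]], proj[[j]], distance)^2
  }
  s / N^2
}

#' Supervised nested Grassmann reduction
#'
#' Finds A in St(m, n) minimizing \code{\link{sng_loss}} by Riemannian
#' descent on Gr(m, n) (the loss carries no offset, so B = 0 in the returned
#' map).  Projected same-class points are drawn together and different-class
#' points pushed apart, sharpening class structure in the reduced space.
#'
#' @inheritParams ng_fit
#' @param labels integer class labels, one per sample.
#' @param nu_w,nu_b neighbor counts, see \code{\link{ng_affinity}}.
#' @param affinity optionally a precomputed affinity matrix (used by the
#'   supervised chain so the graph is built once in the original space).
#' @return an object of classes \code{"sng_fit"}, \code{"ng_fit"},
#'   \code{"nested_map"} with B = 0.
#' @export
sng_fit <- function(data, labels, m, distance = c("projection", "geodesic"),
                    nu_w = NULL, nu_b = 5, affinity = NULL,
                    init = c("pca", "natural", "random"),
                    max_iter = 500, grad_tol = 1e-6, seed = NULL) {
  distance <- match.arg(distance)
  init <- match.arg(init)
  info <- check_dataset(data)
  n <- info$n; p <- info$p; N <- length(data)
  if (m <= p || m >= n) stop_dim("need p < m < n")
  if (is.null(affinity)) affinity <- ng_affinity(data, labels, nu_w, nu_b)

  A0 <- init_basis(data, init, n, m, m, FALSE, info$field, seed)
  par <- list(A = A0)
  obj <- make_sup_objective(data, p, affinity, distance)
  res <- riemann_gd(par, obj$loss, obj$grad, obj$retract,
                    max_iter = max_iter, grad_tol = grad_tol)
  if (!res$converged)
    warning("sng_fit: descent stopped before reaching tolerance; returning best iterate")
  map <- nested_map(res$par$A, NULL, p = p)
  out <- unclass(map)
  out$loss_trace <- res$trace
  out$value <- res$value
  out$converged <- res$converged
  out$iterations <- res$iterations
  out$distance <- distance
  out$affinity <- affinity
  out$labels <- labels
  out$data <- data
  class(out) <- c("sng_fit", "ng_fit", "nested_map")
  out
}

make_sup_objective <- function(data, p, affinity, distance) {
  N <- length(data)
  idx <- which(affinity != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  wts <- affinity[idx]
  if (distance == "projection") {
    loss <- function(par) {
      A <- par$A
      Ms <- lapply(data, function(X) ct(A) %*% X)
      Gs <- lapply(Ms, function(M) solve(ct(M) %*% M))
      s <- 0
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        cross <- ct(Ms[[i]]) %*% Ms[[j]]
        f <- Re(sum(diag(Gs[[i]] %*% cross %*% Gs[[j]] %*% ct(cross))))
        s <- s + 2 * wts[r] * (p - f)
      }
      s / N^2
    }
    grad <- function(par) {
      A <- par$A
      Ms <- lapply(data, function(X) ct(A) %*% X)
      Gs <- lapply(Ms, function(M) solve(ct(M) %*% M))
      Ps <- Map(function(M, G) M %*% G %*% ct(M), Ms, Gs)
      gA <- A * 0
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        Wij <- (Ps[[j]] %*% Ms[[i]] - Ps[[i]] %*% (Ps[[j]] %*% Ms[[i]])) %*% Gs[[i]]
        Wji <- (Ps[[i]] %*% Ms[[j]] - Ps[[j]] %*% (Ps[[i]] %*% Ms[[j]])) %*% Gs[[j]]
        gA <- gA - wts[r] * (4 / N^2) *
          (data[[i]] %*% ct(Wij) + data[[j]] %*% ct(Wji))
      }
      list(A = gA - A %*% (ct(A) %*% gA))
    }
  } else {
    loss <- function(par) sng_loss(par$A, data, affinity, distance = "geodesic")
    grad <- function(par) {
      g <- num_grad(par, loss)
      A <- par$A
      list(A = g$A - A %*% (ct(A) %*% g$A))
    }
  }
  retract <- function(par) {
    par$A <- orthonormalize(par$A)
    par
  }
  list(loss = loss, grad = grad, retract = retract)
}
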