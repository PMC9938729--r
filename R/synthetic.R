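#' Synthetic subspace data near an embedded low-dimensional Grassmannian
#'
#' Seeded generator for the simulation protocol used throughout the package
#' tests: draw N low-dimensional subspaces X_i uniformly on St(p, m), a
#' random embedding frame A uniform on St(m, n) and an offset B with i.i.d.
#' N(0, b_scale) entries; form the clean points
#' X~_i = span(A X_i + (I - A A^H) B) on the embedded submanifold, then
#' perturb each tangentially by a geodesic step of length sigma in a random
#' unit horizontal direction, X_i = Exp_{X~_i}(sigma U_i).  Every sample
#' therefore sits at geodesic distance exactly sigma from the submanifold
#' point it was generated from.
#'
#' Ground truth (the clean points, low-dimensional coordinates and the true
#' (A, B) map) is returned for recovery tests.
#'
#' @param N number of samples.
#' @param n ambient dimension of the observed data.
#' @param m true low ambient dimension (p <= m < n).
#' @param p subspace dimension.
#' @param sigma tangential perturbation magnitude in radians (geodesic).
#' @param b_scale standard deviation of the offset entries.
#' @param field \code{"real"} or \code{"complex"}.
#' @param seed optional integer seed making the draw reproducible.
#' @return object of class \code{"ng_sim"}: \code{data}, \code{clean},
#'   \code{low_points}, \code{truth} (a \code{\link{nested_map}}) and
#'   \code{config}.
#' @export
ng_simulate <- function(N = 50, n = 10, m = 3, p = 1, sigma = 0.5,
                        b_scale = 0.1, field = c("real", "complex"),
                        seed = NULL) {
  field <- match.arg(field)
  if (!(p <= m && m < n)) stop_dim("need p <= m < n")
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (N < 1) stop_dim("N must be at least 1")
  with_seed(seed, {
    A <- orthonormalize(rnorm_mat(n, m, field))
    B <- rnorm_mat(n, p, field) * b_scale
    truth <- nested_map(A, B)
    low <- lapply(seq_len(N), function(i) orthonormalize(rnorm_mat(m, p, field)))
    clean <- lapply(low, function(X) ng_embed(truth, X))
    data <- if (sigma == 0) clean else lapply(clean, function(Xt) {
      U <- {
        G <- rnorm_mat(n, p, field)
        H <- G - Xt %*% (ct(Xt) %*% G)
        H / fnorm(H)
      }
      gr_exp(Xt, sigma * U)
    })
    structure(list(data = data, clean = clean, low_points = low,
                   truth = truth,
                   config = list(N = N, n = n, m = m, p = p, sigma = sigma,
                                 b_scale = b_scale, field = field, seed = seed)),
              class = "ng_sim")
  })
}

#' @export
print.ng_sim <- function(x, ...) {
  cf <- x$config
  cat(sprintf("Synthetic Grassmann dataset: N = %d points of Gr(%d, %d) [%s]\n",
              cf$N, cf$p, cf$n, cf$field))
  cat(sprintf("  true submanifold Gr(%d, %d); tangential noise sigma = %g\n",
              cf$p, cf$m, cf$sigma))
  invisible(x)
}

#' Two-class synthetic mixture
#'
#' Convenience generator for supervised tests (beyond the unsupervised
#' simulation protocol): two classes generated around two independent
#' embedded submanifolds with distinct (A, B) truths, labels by component.
#'
#' @param N_per_class samples per class.
#' @inheritParams ng_simulate
#' @return list with \code{data}, \code{labels} and the two \code{ng_sim}
#'   components.
#' @export
ng_simulate_classes <- function(N_per_class = 25, n = 10, m = 3, p = 1,
                                sigma = 0.1, b_scale = 0.1,
                                field = c("real", "complex"), seed = NULL) {
  field <- match.arg(field)
  seeds <- if (is.null(seed)) c(NULL, NULL) else c(seed, seed + 1L)
  s1 <- ng_simulate(N_per_class, n, m, p, sigma, b_scale, field,
                    seed = if (is.null(seed)) NULL else seeds[1])
  s2 <- ng_simulate(N_per_class, n, m, p, sigma, b_scale, field,
                    seed = if (is.null(seed)) NULL else seeds[2])
  list(data = c(s1$data, s2$data),
       labels = rep(1:2, each = N_per_class),
       components = list(s1, s2))
}
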