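#' Principal geodesic analysis (tangent PCA) on the Grassmann manifold
#'
#' The standard comparison baseline: compute the Fréchet mean of the data,
#' lift every sample to the tangent space at the mean with the log map, and
#' run ordinary (centered, unscaled) PCA on the vectorized tangent
#' coordinates.  Complex tangent matrices are flattened to interleaved
#' real/imaginary coordinates, exactly as the principal scores are, so the
#' two methods report explained variance on comparable scales.
#'
#' @param data list of n x p orthonormal-column matrices within the
#'   convergence region of the Fréchet mean (no sample at a cut locus).
#' @param k number of principal components to retain (at most the manifold
#'   dimension).
#' @return object of class \code{"pga_fit"}: \code{mean}, \code{components}
#'   (list of horizontal tangent matrices at the mean, mutually orthogonal),
#'   \code{cumvar} (cumulative explained-variance ratios for the first k
#'   components), \code{sdev}, and the tangent coordinates \code{x}.
#' @export
pga_fit <- function(data, k = 3L) {
  info <- check_dataset(data)
  dim_manifold <- info$p * (info$n - info$p) * (if (info$field == "complex") 2L else 1L)
  if (k > dim_manifold) stop_dim("k exceeds the manifold dimension")
  fm <- frechet_mean(data)
  if (fm$variance < 1e-14) stop("zero variance: all samples coincide", call. = FALSE)
  mu <- fm$mean
  logs <- vector("list", length(data))
  for (i in seq_along(data)) {
    logs[[i]] <- tryCatch(gr_log(mu, data[[i]]),
                          error = function(e)
                            stop(sprintf("sample %d lies at the cut locus of the mean", i),
                                 call. = FALSE))
  }
  cplx <- info$field == "complex"
  tanmat <- t(vapply(logs, function(H) {
    v <- as.vector(H)
    if (cplx) flatten_complex(v) else v
  }, numeric(if (cplx) 2 * info$n * info$p else info$n * info$p)))
  pc <- stats::prcomp(tanmat, center = TRUE, scale. = FALSE)
  ratios <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  keep <- seq_len(min(k, ncol(pc$rotation)))
  comps <- lapply(keep, function(j) {
    v <- pc$rotation[, j]
    H <- if (cplx) unflatten_complex(v, info$n, info$p) else matrix(v, info$n, info$p)
    # keep components exactly horizontal at the mean
    H - mu %*% (ct(mu) %*% H)
  })
  structure(list(mean = mu, variance = fm$variance,
                 components = comps,
                 cumvar = ratios[seq_len(k)],
                 sdev = pc$sdev, x = pc$x,
                 n = info$n, p = info$p, field = info$field,
                 k = k, call = match.call()),
            class = "pga_fit")
}

unflatten_complex <- function(v, n, p) {
  re <- v[seq(1, length(v), by = 2)]
  im <- v[seq(2, length(v), by = 2)]
  matrix(complex(real = re, imaginary = im), n, p)
}

#' @export
print.pga_fit <- function(x, ...) {
  cat(sprintf("Tangent PCA (PGA) on Gr(%d, %d) [%s]\n", x$p, x$n, x$field))
  cat(sprintf("  Fréchet variance %.4g; cumulative explained variance (k = %d): %s\n",
              x$variance, x$k,
              paste(sprintf("%.3f", x$cumvar), collapse = ", ")))
  invisible(x)
}

#' Reconstruct points from leading PGA components
#'
#' Maps truncated tangent-space coordinates back to the manifold through the
#' exponential map at the mean.
#'
#' @param object a \code{\link{pga_fit}}.
#' @param coords numeric vector of coefficients (length <= number of stored
#'   components).
#' @return an orthonormal-column matrix.
#' @export
pga_reconstruct <- function(object, coords) {
  H <- object$mean * 0
  for (j in seq_along(coords)) H <- H + coords[j] * object$components[[j]]
  gr_exp(object$mean, H)
}
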