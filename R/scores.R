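#' Principal scores for a nested Grassmann chain
#'
#' Each one-dimension-drop projection pi_m: Gr(p, m+1) -> Gr(p, m) loses
#' exactly p (real) or 2p (complex) real dimensions; the principal score of a
#' sample records where it sat in the fiber over its projection.  With
#' X~ = iota(pi(X)) the reconstruction, the fiber direction is coordinatized
#' by V = X^H A_perp (A_perp the unit vector completing the step's column
#' space), V is normalized to unit length, and the score vector is
#' d_g(X~, X) * V, so its Euclidean norm is the per-step reconstruction
#' distance.  Complex score vectors are flattened to 2p reals, interleaved
#' (Re v_1, Im v_1, ..., Re v_p, Im v_p).
#'
#' At the bottom of the chain the score relative to the nested Grassmann
#' mean is recorded: on real Gr(1, 2) the signed geodesic distance in the
#' angle chart (1 column); on complex Gr(1, 2) the tangent coordinates of
#' the log map at the NGM (2 columns).  The total number of real columns is
#' therefore exactly the manifold dimension: p(n - p) real, 2p(n - p)
#' complex.
#'
#' @param model a fitted \code{\link{png_fit}} object.
#' @param data dataset in the original space; defaults to the training data.
#' @return an N x p(n-p) (real) or N x 2p(n-p) (complex) numeric matrix with
#'   named columns; attribute \code{"raw_norms"} holds the unnormalized
#'   |V| per step for audit.
#' @export
png_scores <- function(model, data = NULL) {
  if (is.null(data)) data <- model$data
  N <- length(data)
  blocks <- list()
  norms <- list()
  finals <- vector("list", N)
  chains <- lapply(data, function(X) push_chain(model, X))
  for (i in seq_along(model$steps)) {
    step <- model$steps[[i]]
    pts <- lapply(chains, `[[`, i)
    sb <- step_scores(step, pts)
    colnames(sb$matrix) <- paste0("s", step$high, "to", step$low, "_",
                                  colnames(sb$matrix))
    blocks[[length(blocks) + 1L]] <- sb$matrix
    norms[[length(norms) + 1L]] <- sb$raw_norms
  }
  bottoms <- lapply(chains, function(ch) attr(ch, "final"))
  fin <- signed_score_gr12(bottoms, model$ngm)
  fin <- as.matrix(fin)
  colnames(fin) <- if (ncol(fin) == 1) "ngm" else c("ngm_re", "ngm_im")
  out <- do.call(cbind, c(blocks, list(fin)))
  rownames(out) <- names(data)
  attr(out, "raw_norms") <- do.call(cbind, norms)
  out
}

#' Per-step principal scores
#'
#' Scores of a set of Gr(p, m+1) points under a single fitted chain step;
#' see \code{\link{png_scores}}.
#'
#' @param step one element of \code{png_fit()$steps} (a list with the fitted
#'   \code{map} and its completion vector \code{A_perp}).
#' @param data list of (m+1) x p orthonormal-column matrices.
#' @return list with \code{matrix} (N x p real or N x 2p flattened complex
#'   scores) and \code{raw_norms} (|V| before normalization).
#' @export
step_scores <- function(step, data) {
  map <- step$map
  Ap <- step$A_perp
  p <- ncol(data[[1]])
  cplx <- is.complex(data[[1]]) || is.complex(Ap)
  q <- if (cplx) 2L * p else p
  N <- length(data)
  out <- matrix(0, N, q)
  rn <- numeric(N)
  for (i in seq_len(N)) {
    X <- data[[i]]
    Xt <- ng_reconstruct(map, X)
    d <- gr_dist(Xt, X, "geodesic")
    V <- as.vector(ct(X) %*% Ap)
    rn[i] <- sqrt(sum(Mod(V)^2))
    if (rn[i] > 1e-12 && d > 0) {
      V <- V / rn[i]
      sc <- d * V
    } else {
      sc <- rep(if (cplx) 0 + 0i else 0, p)
    }
    out[i, ] <- if (cplx) flatten_complex(sc) else Re(sc)
  }
  colnames(out) <- if (cplx) {
    as.vector(rbind(paste0("re", seq_len(p)), paste0("im", seq_len(p))))
  } else paste0("c", seq_len(p))
  list(matrix = out, raw_norms = rn)
}

# interleave real and imaginary parts per coordinate
flatten_complex <- function(v) {
  as.vector(rbind(Re(v), Im(v)))
}

#' Signed score on Gr(1, 2) relative to the nested Grassmann mean
#'
#' Real case: identify Gr(1, 2) with the angle chart phi in [0, pi); the
#' score is the signed wrapped difference phi_i - phi_ngm mapped to
#' (-pi/2, pi/2], whose absolute value is the geodesic distance to the NGM.
#' Complex case (ambient C^2): the 2-dimensional tangent coordinate of the
#' log map at the NGM against a fixed unit horizontal basis, flattened to
#' (Re, Im); its Euclidean norm is the geodesic distance.
#'
#' @param data list of 2 x 1 basis matrices (real or complex).
#' @param ngm 2 x 1 basis matrix, the nested Grassmann mean.
#' @return N-vector (real) or N x 2 matrix (complex).
#' @export
signed_score_gr12 <- function(data, ngm) {
  stopifnot(nrow(ngm) == 2, ncol(ngm) == 1)
  if (is.complex(ngm) || is.complex(data[[1]])) {
    u <- canonical_line(gr_complement(ngm))   # fixed horizontal basis at ngm
    out <- t(vapply(data, function(X) {
      H <- gr_log(ngm, X)
      h <- sum(Conj(u) * H)
      c(Re(h), Im(h))
    }, numeric(2)))
    return(out)
  }
  ang <- function(x) {
    v <- canonical_line(x)
    (atan2(v[2, 1], v[1, 1])) %% pi
  }
  a0 <- ang(ngm)
  vapply(data, function(X) {
    d <- (ang(X) - a0) %% pi
    if (d > pi / 2) d <- d - pi
    d
  }, numeric(1))
}

#' PCA of principal scores
#'
#' Centered, unscaled principal component analysis of a score table; the
#' cumulative explained-variance ratios of the leading components are the
#' "principal components of PNG" used to compare against PGA.
#'
#' @param scores numeric score matrix (samples x score columns), e.g. from
#'   \code{\link{png_scores}}.
#' @param k number of leading components to report.
#' @return list with \code{components} (loadings, columns = components),
#'   \code{cumvar} (cumulative explained-variance ratios, length k),
#'   \code{sdev}, and the rotated \code{x}.
#' @export
score_pca <- function(scores, k = min(3L, ncol(scores))) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("at least two samples required", call. = FALSE)
  if (k > ncol(scores)) stop_dim("k exceeds the number of score columns")
  pc <- stats::prcomp(scores, center = TRUE, scale. = FALSE)
  ratios <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  list(components = pc$rotation[, seq_len(k), drop = FALSE],
       cumvar = ratios[seq_len(k)],
       sdev = pc$sdev,
       x = pc$x)
}
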