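#' Principal nested Grassmann analysis
#'
#' Fits the full principal nested Grassmann (PNG) chain
#' \deqn{Gr(p,n) \to Gr(p,n-1) \to \cdots \to Gr(p,p+1) \cong Gr(1,p+1)
#'   \to \cdots \to Gr(1,2)}
#' by a sequence of one-dimension-drop nested Grassmann reductions
#' (\code{\link{ng_fit}}, or their supervised counterparts when labels are
#' given), switching from Gr(p, p+1) to Gr(1, p+1) through the orthogonal
#' complement, and ending with the Fréchet mean on Gr(1, 2) -- the nested
#' Grassmann mean (NGM).  Per-level losses and Fréchet variances are
#' recorded; principal scores are obtained with \code{\link{png_scores}} (or
#' \code{predict}).
#'
#' @param data list of n x p orthonormal-column matrices, n >= 3.
#' @param distance distance driving each fit; see \code{\link{ng_fit}}.
#' @param labels optional integer class labels; when given, every level is
#'   fitted with the supervised loss of \code{\link{sng_fit}} (sPNG).  The
#'   neighbor affinity is built once from the original data and held fixed
#'   across levels unless \code{rebuild_affinity} is TRUE.
#' @param nu_w,nu_b within/between-class neighbor counts for the supervised
#'   affinity (see \code{\link{ng_affinity}}).
#' @param rebuild_affinity rebuild the affinity from the projected data at
#'   each level instead of reusing the original-space affinity.
#' @param max_iter,grad_tol,seed passed to each per-level fit.
#' @return an object of class \code{"png_fit"} with components \code{steps}
#'   (one per fitted projection: the map, the completion vector of its
#'   column space, loss and the Fréchet variance of the projected data),
#'   \code{ngm}, \code{variance0}, and bookkeeping fields.
#' @export
png_fit <- function(data, distance = c("projection", "geodesic"),
                    labels = NULL, nu_w = NULL, nu_b = 5,
                    rebuild_affinity = FALSE,
                    max_iter = 500, grad_tol = 1e-6, seed = NULL) {
  distance <- match.arg(distance)
  info <- check_dataset(data)
  n <- info$n; p <- info$p
  if (n < 3) stop_dim("the chain requires ambient dimension n >= 3")
  supervised <- !is.null(labels)
  aff <- NULL
  if (supervised) aff <- ng_affinity(data, labels, nu_w = nu_w, nu_b = nu_b)

  var0 <- frechet_variance(data)
  cur <- data
  cur_p <- p
  k <- n
  steps <- list()
  swap_after <- NA_integer_
  while (k > 2) {
    if (cur_p > 1 && k == cur_p + 1) {
      cur <- lapply(cur, complement_swap)
      cur_p <- 1L
      swap_after <- length(steps)
      next
    }
    if (supervised) {
      if (rebuild_affinity) aff <- ng_affinity(cur, labels, nu_w = nu_w, nu_b = nu_b)
      fit <- sng_fit(cur, labels, m = k - 1, distance = distance,
                     affinity = aff, max_iter = max_iter,
                     grad_tol = grad_tol, seed = seed)
    } else {
      fit <- ng_fit(cur, m = k - 1, distance = distance,
                    max_iter = max_iter, grad_tol = grad_tol, seed = seed)
    }
    fit$data <- NULL
    cur <- lapply(cur, function(X) ng_project(fit, X))
    k <- k - 1
    steps[[length(steps) + 1L]] <- list(
      map = fit,
      A_perp = gr_complement(fit$A),
      high = k + 1L, low = k, sub = cur_p,
      loss = fit$value,
      variance = NA_real_)
    # expressed variance at this level: Fréchet variance of the data
    # projected onto the current submanifold, measured in the top space
    top <- lift_chain(steps, swap_after, cur)
    steps[[length(steps)]]$variance <- frechet_variance(top)
  }
  fm <- frechet_mean(cur)
  structure(list(steps = steps, swap_after = swap_after,
                 ngm = fm$mean, ngm_variance = fm$variance,
                 variance0 = var0,
                 n = n, p = p, field = info$field, N = length(data),
                 distance = distance, supervised = supervised,
                 data = data, labels = labels,
                 call = match.call()),
            class = "png_fit")
}

#' @export
print.png_fit <- function(x, ...) {
  cat(sprintf("Principal nested Grassmann%s fit on Gr(%d, %d) [%s], N = %d\n",
              if (x$supervised) " (supervised)" else "", x$p, x$n, x$field, x$N))
  cat(sprintf("  %d projection steps down to Gr(1, 2); NGM variance %.4g\n",
              length(x$steps), x$ngm_variance))
  cat(sprintf("  original Fréchet variance %.4g\n", x$variance0))
  invisible(x)
}

#' @export
summary.png_fit <- function(object, ...) {
  ev <- explained_variance(object)
  out <- list(levels = ev, model = object)
  class(out) <- "summary.png_fit"
  out
}

#' @export
print.summary.png_fit <- function(x, ...) {
  print(x$model)
  cat("\nPer-level reconstruction loss and expressed variance:\n")
  print(x$levels, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
explained_variance.png_fit <- function(object, data = NULL, ...) {
  if (object$variance0 < 1e-14)
    stop("degenerate dataset: zero variance", call. = FALSE)
  lv <- data.frame(
    sub_dim = vapply(object$steps, function(s) as.integer(s$sub), integer(1)),
    ambient = vapply(object$steps, function(s) as.integer(s$low), integer(1)),
    loss = vapply(object$steps, `[[`, numeric(1), "loss"),
    variance = vapply(object$steps, `[[`, numeric(1), "variance"))
  lv$variance_ratio <- pmin(lv$variance / object$variance0, 1)
  lv
}

#' @export
plot.png_fit <- function(x, ...) {
  ev <- explained_variance(x)
  plot(rev(seq_len(nrow(ev))), rev(ev$variance_ratio), type = "b",
       xlab = "chain level (low to high dimension)",
       ylab = "ratio of expressed variance",
       main = "Expressed variance along the PNG chain", ...)
  invisible(x)
}

#' @export
predict.png_fit <- function(object, newdata = NULL, ...) {
  png_scores(object, newdata)
}

# embed points living after step `from` (default: the last fitted step) back
# up to the original space, complementing across the Gr(p, p+1) = Gr(1, p+1)
# switch
lift_chain <- function(steps, swap_after, pts, from = length(steps)) {
  for (j in seq(from, 1L)) {
    pts <- lapply(pts, function(X) ng_embed(steps[[j]]$map, X))
    if (!is.na(swap_after) && swap_after == j - 1L)
      pts <- lapply(pts, gr_complement)
  }
  pts
}

# push one sample down the chain, returning the per-level representatives
# (list indexed like steps; element i is the point BEFORE step i is applied,
# already complement-swapped when the swap precedes step i)
push_chain <- function(model, X) {
  out <- vector("list", length(model$steps))
  cur <- X
  for (i in seq_along(model$steps)) {
    if (!is.na(model$swap_after) && model$swap_after == i - 1L &&
        ncol(cur) > 1)
      cur <- complement_swap(cur)
    out[[i]] <- cur
    cur <- ng_project(model$steps[[i]]$map, cur)
  }
  attr(out, "final") <- cur
  out
}
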