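# Internal Riemannian steepest descent with Barzilai-Borwein step sizes and
# a monotone backtracking (Armijo) line search.
#
# Parameters are lists of matrices; `grad` must return the Riemannian
# gradient already projected onto the tangent space of each block, and
# `retract` maps a perturbed parameter list back onto the manifold (QR
# re-orthonormalization for Stiefel/Grassmann blocks, identity for Euclidean
# blocks).  The loss trace is nonincreasing by construction.

par_axpy <- function(par, t, dir) {
  out <- par
  for (k in seq_along(par)) out[[k]] <- par[[k]] + t * dir[[k]]
  out
}

par_inner <- function(x, y) {
  s <- 0
  for (k in seq_along(x)) s <- s + re_inner(x[[k]], y[[k]])
  s
}

par_norm <- function(x) sqrt(par_inner(x, x))

riemann_gd <- function(par, loss, grad, retract,
                       max_iter = 500, grad_tol = 1e-6,
                       step0 = 1, min_step = 1e-14, loss_tol = 1e-14) {
  f <- loss(par)
  trace <- f
  g <- grad(par)
  step <- step0
  converged <- FALSE
  prev_par <- NULL; prev_g <- NULL
  for (it in seq_len(max_iter)) {
    gn <- par_norm(g)
    if (gn <= grad_tol) { converged <- TRUE; break }
    # Barzilai-Borwein step from the previous accepted move
    if (!is.null(prev_par)) {
      s <- Map(function(a, b) a - b, par, prev_par)
      y <- Map(function(a, b) a - b, g, prev_g)
      sy <- par_inner(s, y)
      if (is.finite(sy) && sy > 1e-16) {
        step <- par_inner(s, s) / sy
        step <- min(max(step, 1e-10), 1e4)
      }
    }
    dir <- lapply(g, function(x) -x)
    t <- step
    accepted <- FALSE
    for (ls in 1:60) {
      cand <- retract(par_axpy(par, t, dir))
      fc <- loss(cand)
      if (is.finite(fc) && fc <= f - 1e-4 * t * gn^2) { accepted <- TRUE; break }
      t <- t / 2
      if (t < min_step) break
    }
    if (!accepted) break
    prev_par <- par; prev_g <- g
    par <- cand
    dec <- f - fc
    f <- fc
    trace <- c(trace, f)
    g <- grad(par)
    if (dec < loss_tol * max(1, abs(f))) {
      converged <- par_norm(g) <= max(grad_tol, 1e2 * grad_tol)
      break
    }
  }
  list(par = par, value = f, trace = trace, converged = converged,
       iterations = length(trace) - 1L, grad_norm = par_norm(grad(par)))
}

# central-difference Euclidean gradient over the real coordinates of a
# parameter list (real and imaginary parts separately for complex blocks)
num_grad <- function(par, loss, h = 1e-6) {
  g <- par
  for (k in seq_along(par)) {
    P <- par[[k]]
    G <- array(0, dim = dim(P))
    cplx <- is.complex(P)
    if (cplx) G <- G + 0i
    for (j in seq_along(P)) {
      Pp <- P; Pm <- P
      Pp[j] <- Pp[j] + h; Pm[j] <- Pm[j] - h
      parp <- par; parm <- par
      parp[[k]] <- Pp; parm[[k]] <- Pm
      d_re <- (loss(parp) - loss(parm)) / (2 * h)
      if (cplx) {
        Pp <- P; Pm <- P
        Pp[j] <- Pp[j] + h * 1i; Pm[j] <- Pm[j] - h * 1i
        parp[[k]] <- Pp; parm[[k]] <- Pm
        d_im <- (loss(parp) - loss(parm)) / (2 * h)
        G[j] <- complex(real = d_re, imaginary = d_im)
      } else {
        G[j] <- d_re
      }
    }
    # Riesz convention: loss change = re_inner(G, dP)
    g[[k]] <- G
  }
  g
}
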