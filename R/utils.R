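# Internal numerical helpers shared across the package.

# conjugate transpose; reduces to t() for real matrices
ct <- function(X) Conj(t(X))

fnorm <- function(X) sqrt(sum(Mod(X)^2))

# real inner product on matrix spaces; for complex arguments this is the
# canonical real part of the Hermitian inner product
re_inner <- function(X, Y) sum(Re(Conj(X) * Y))

is_complex_mat <- function(X) is.complex(X)

field_of <- function(X) if (is.complex(X)) "complex" else "real"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Gaussian matrix over the requested field
rnorm_mat <- function(n, p, field = c("real", "complex")) {
  field <- match.arg(field)
  if (field == "real") {
    matrix(stats::rnorm(n * p), n, p)
  } else {
    matrix(complex(real = stats::rnorm(n * p), imaginary = stats::rnorm(n * p)), n, p)
  }
}

# canonical representative of a 1-dimensional subspace: phase chosen so the
# largest-modulus entry is real and positive
canonical_line <- function(x) {
  x <- as.matrix(x)
  i <- which.max(Mod(x))
  ph <- x[i, 1] / Mod(x[i, 1])
  x * Conj(ph)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# thin QR factors by modified Gram-Schmidt with one reorthogonalization
# pass: deterministic, never pivots (base qr() column-pivots for complex
# input), diagonal of R real and positive
qr_factors <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); p <- ncol(M)
  Q <- M
  R <- matrix(if (is.complex(M)) 0 + 0i else 0, p, p)
  for (j in seq_len(p)) {
    v <- M[, j]
    if (j > 1) {
      Qj <- Q[, seq_len(j - 1), drop = FALSE]
      for (pass in 1:2) {
        c1 <- ct(Qj) %*% v
        v <- v - Qj %*% c1
        R[seq_len(j - 1), j] <- R[seq_len(j - 1), j] + c1
      }
    }
    nrm <- fnorm(v)
    if (nrm < .Machine$double.xmin^0.5)
      stop("degenerate input: rank-deficient matrix", call. = FALSE)
    R[j, j] <- nrm
    Q[, j] <- v / nrm
  }
  list(Q = Q, R = R)
}

# upper-triangular Cholesky factor (R^H R = G) of a Hermitian positive
# definite matrix, real or complex; base chol() is real-only
chol_hermitian <- function(G) {
  p <- nrow(G)
  R <- G * 0
  for (j in seq_len(p)) {
    s <- G[j, j] - sum(Mod(R[seq_len(j - 1), j])^2)
    R[j, j] <- sqrt(Re(s))
    if (j < p) for (k in (j + 1):p) {
      acc <- G[j, k] - sum(Conj(R[seq_len(j - 1), j]) * R[seq_len(j - 1), k])
      R[j, k] <- acc / R[j, j]
    }
  }
  R
}

stop_dim <- function(msg) stop(msg, call. = FALSE)
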