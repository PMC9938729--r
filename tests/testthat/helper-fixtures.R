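# shared fixtures: everything generated in code, seeded

rand_subspace <- function(p, n, field = "real", seed = NULL) {
  runif_stiefel(p, n, field, seed = seed)
}

# a pair with all principal angles strictly below a bound (for log-map tests)
rand_close_pair <- function(p, n, field = "real", scale = 0.3, seed = NULL) {
  with_seed_local(seed, {
    X <- runif_stiefel(p, n, field)
    H <- random_unit_tangent(X)
    Y <- gr_exp(X, scale * H)
    list(X = X, Y = Y)
  })
}

with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

rand_nested_map <- function(p, m, n, field = "real", b_scale = 0, seed = NULL) {
  with_seed_local(seed, {
    A <- runif_stiefel(m, n, field)
    if (b_scale > 0) {
      B <- nestedGrassmann:::rnorm_mat(n, p, field) * b_scale
      nested_map(A, B)
    } else {
      nested_map(A, NULL, p = p)
    }
  })
}

push_chain_local <- function(model, X) nestedGrassmann:::push_chain(model, X)

withr_local_tempdir <- function() {
  d <- tempfile("fixture")
  dir.create(d)
  d
}

pairwise_dist <- function(data, kind = "geodesic") {
  N <- length(data)
  D <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    D[i, j] <- D[j, i] <- gr_dist(data[[i]], data[[j]], kind)
  D
}
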