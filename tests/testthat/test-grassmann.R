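test_that("orthonormalize returns a deterministic basis spanning the input", {
  # already orthonormal input is unchanged
  E <- diag(3)[, 1:2]
  expect_equal(orthonormalize(E), E)
  # column scaling is removed
  M <- cbind(c(2, 0, 0), c(0, 3, 0))
  expect_equal(orthonormalize(M), diag(3)[, 1:2])
  # complex random input: orthonormal and same span as an SVD-based oracle
  set.seed(11)
  Mc <- matrix(complex(real = rnorm(12), imaginary = rnorm(12)), 6, 2)
  Q <- orthonormalize(Mc)
  expect_lt(max(Mod(Conj(t(Q)) %*% Q - diag(2))), 1e-12)
  U <- svd(Mc)$u  # independent orthonormalization of the same column space
  expect_lt(max(principal_angles(Q, U)), 1e-10)
  # rank-deficient input errors
  expect_error(orthonormalize(cbind(1:3, 2 * (1:3))), "degenerate")
})

test_that("principal angles match planar and orthogonal reference cases", {
  X <- rand_subspace(2, 6, seed = 1)
  expect_lt(max(principal_angles(X, X)), 1e-12)
  t <- pi / 4
  e1 <- matrix(c(1, 0), 2, 1)
  vt <- matrix(c(cos(t), sin(t)), 2, 1)
  expect_equal(principal_angles(e1, vt), t, tolerance = 1e-12)
  E12 <- diag(4)[, 1:2]; E34 <- diag(4)[, 3:4]
  expect_equal(principal_angles(E12, E34), c(pi / 2, pi / 2), tolerance = 1e-12)
  expect_error(principal_angles(X, rand_subspace(2, 5, seed = 2)), "mismatch")
})

test_that("geodesic and projection distances agree with their formulas", {
  t <- pi / 4
  e1 <- matrix(c(1, 0), 2, 1)
  vt <- matrix(c(cos(t), sin(t)), 2, 1)
  expect_equal(gr_dist(e1, vt, "geodesic"), pi / 4, tolerance = 1e-12)
  expect_equal(gr_dist(e1, vt, "projection"), sin(pi / 4), tolerance = 1e-12)
  for (field in c("real", "complex")) {
    X <- rand_subspace(2, 6, field, seed = 3)
    Y <- rand_subspace(2, 6, field, seed = 4)
    expect_equal(gr_dist(X, Y), 0 + gr_dist(Y, X), tolerance = 1e-10)
    # projection distance equals the projector-difference Frobenius norm
    PX <- X %*% Conj(t(X)); PY <- Y %*% Conj(t(Y))
    expect_equal(gr_dist(X, Y, "projection"),
                 sqrt(sum(Mod(PX - PY)^2)) / sqrt(2), tolerance = 1e-10)
    expect_equal(gr_dist(X, X, "projection"), 0, tolerance = 1e-12)
  }
  expect_error(gr_dist(e1, vt, "chordal"))
})

test_that("projection distance lower-bounds the geodesic distance and matches it locally", {
  for (i in 1:10) {
    pr <- rand_close_pair(2, 7, scale = runif(1, 0.5, 1.5), seed = 100 + i)
    expect_lte(gr_dist(pr$X, pr$Y, "projection"), gr_dist(pr$X, pr$Y, "geodesic"))
  }
  pr <- rand_close_pair(2, 7, scale = 0.03, seed = 5)
  dg <- gr_dist(pr$X, pr$Y, "geodesic")
  dp <- gr_dist(pr$X, pr$Y, "projection")
  expect_lt(dg, 0.05)
  expect_lt(abs(dg / dp - 1), 1e-3)
})

test_that("exp and log are mutually inverse along geodesics", {
  X <- matrix(c(1, 0), 2, 1)
  expect_equal(gr_exp(X, matrix(0, 2, 1)), X)
  t <- 0.7
  Y <- gr_exp(X, matrix(c(0, t), 2, 1))
  expect_lt(max(principal_angles(Y, matrix(c(cos(t), sin(t)), 2, 1))), 1e-12)
  expect_equal(fnorm_t <- sqrt(sum(gr_log(X, Y)^2)), t, tolerance = 1e-10)
  for (field in c("real", "complex")) {
    for (i in 1:5) {
      pr <- rand_close_pair(2, 5, field, scale = runif(1, 0.1, 0.9 * pi / 2),
                            seed = 200 + i)
      H <- gr_log(pr$X, pr$Y)
      expect_lt(max(principal_angles(gr_exp(pr$X, H), pr$Y)), 1e-9)
      expect_equal(sqrt(sum(Mod(H)^2)), gr_dist(pr$X, pr$Y), tolerance = 1e-8)
    }
  }
  # small tangent: geodesic speed
  X <- rand_subspace(2, 6, seed = 6)
  H <- 1e-3 * random_unit_tangent(X, seed = 7)
  expect_equal(gr_dist(X, gr_exp(X, H)), 1e-3, tolerance = 1e-6)
  # errors: non-horizontal tangent, cut locus
  expect_error(gr_exp(X, X), "horizontal")
  expect_error(gr_log(diag(4)[, 1:2], diag(4)[, 3:4]), "cut locus")
})

test_that("operations are invariant to the choice of basis representative", {
  for (field in c("real", "complex")) {
    X <- rand_subspace(2, 6, field, seed = 8)
    Y <- rand_subspace(2, 6, field, seed = 9)
    O <- runif_stiefel(2, 2, field, seed = 10)   # unitary 2x2
    XO <- X %*% O
    expect_lt(max(abs(principal_angles(X, Y) - principal_angles(XO, Y))), 1e-10)
    expect_equal(gr_dist(XO, Y), gr_dist(X, Y), tolerance = 1e-10)
    expect_lt(max(principal_angles(X, XO)), 1e-7)
  }
})

test_that("Frechet mean handles degenerate, two-point and sampled configurations", {
  X <- rand_subspace(1, 4, seed = 12)
  fm <- frechet_mean(list(X, X, X))
  expect_lt(max(principal_angles(fm$mean, X)), 1e-10)
  expect_equal(fm$variance, 0)
  # two points on Gr(1,2): mean at the midpoint angle
  t <- 0.8
  A <- matrix(c(1, 0), 2, 1); B <- matrix(c(cos(t), sin(t)), 2, 1)
  fm2 <- frechet_mean(list(A, B))
  expect_equal(gr_dist(fm2$mean, A), t / 2, tolerance = 1e-8)
  expect_equal(gr_dist(fm2$mean, B), t / 2, tolerance = 1e-8)
})

test_that("Frechet mean on Gr(1,2) matches a grid-search oracle", {
  set.seed(13)
  angs <- runif(20, 0, 1.2)                 # points within a convex arc
  pts <- lapply(angs, function(a) matrix(c(cos(a), sin(a)), 2, 1))
  fm <- frechet_mean(pts)
  # independent oracle: dense grid minimization of the Karcher objective
  grid <- seq(0, pi, length.out = 1e5)
  obj <- vapply(grid, function(g) {
    d <- abs(((angs - g + pi / 2) %% pi) - pi / 2)
    mean(d^2)
  }, numeric(1))
  gstar <- grid[which.min(obj)]
  mu_ang <- atan2(fm$mean[2, 1], fm$mean[1, 1]) %% pi
  expect_lt(abs(((mu_ang - gstar + pi / 2) %% pi) - pi / 2), 1e-3)
  expect_equal(fm$variance, min(obj), tolerance = 1e-6)
})

test_that("uniform Stiefel draws are orthonormal, seeded and moment-correct", {
  Q <- runif_stiefel(4, 4, "real", seed = 14)
  expect_lt(max(abs(t(Q) %*% Q - diag(4))), 1e-12)
  expect_identical(runif_stiefel(2, 5, seed = 15), runif_stiefel(2, 5, seed = 15))
  expect_error(runif_stiefel(6, 5), "exceed")
  # E[X X^T] = (p/m) I for the invariant distribution on St(2, 5)
  set.seed(16)
  S <- matrix(0, 5, 5)
  for (i in 1:20000) {
    X <- orthonormalize(matrix(rnorm(10), 5, 2))
    S <- S + X %*% t(X)
  }
  expect_lt(max(abs(S / 20000 - 0.4 * diag(5))), 0.02)
})

test_that("random unit tangents are horizontal, normalized and unit-speed", {
  for (field in c("real", "complex")) {
    X <- rand_subspace(2, 6, field, seed = 17)
    U <- random_unit_tangent(X, seed = 18)
    expect_lt(max(Mod(Conj(t(X)) %*% U)), 1e-12)
    expect_equal(sqrt(sum(Mod(U)^2)), 1, tolerance = 1e-12)
    expect_equal(gr_dist(X, gr_exp(X, 0.3 * U)), 0.3, tolerance = 1e-8)
  }
})

test_that("orthogonal complement swap realizes Gr(p, p+1) = Gr(1, p+1)", {
  E <- diag(3)[, 1:2]
  expect_equal(abs(complement_swap(E)), matrix(c(0, 0, 1), 3, 1))
  # involution through the general complement
  X <- rand_subspace(2, 3, seed = 19)
  back <- gr_complement(complement_swap(X))
  expect_lt(max(principal_angles(back, X)), 1e-10)
  # complement pairs preserve geodesic distances
  Y <- rand_subspace(2, 3, seed = 20)
  expect_equal(gr_dist(complement_swap(X), complement_swap(Y)),
               gr_dist(X, Y), tolerance = 1e-10)
  expect_error(complement_swap(rand_subspace(1, 3, seed = 21)), "ambient")
})
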