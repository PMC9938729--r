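test_that("the affinity matrix matches brute-force neighbor lists", {
  # 6 points on Gr(1,3): two tight clusters far apart, labels by cluster
  base1 <- matrix(c(1, 0, 0), 3, 1)
  base2 <- matrix(c(0, 0, 1), 3, 1)
  mk <- function(base, eps, dir) gr_exp(base, eps * dir)
  d1 <- random_unit_tangent(base1, seed = 1)
  d2 <- random_unit_tangent(base2, seed = 2)
  data <- list(mk(base1, 0.00, d1), mk(base1, 0.05, d1), mk(base1, 0.11, d1),
               mk(base2, 0.00, d2), mk(base2, 0.04, d2), mk(base2, 0.09, d2))
  labels <- c(1, 1, 1, 2, 2, 2)
  a <- ng_affinity(data, labels, nu_w = 1, nu_b = 1)
  # independent brute force from the distance matrix
  D <- pairwise_dist(data)
  gw <- matrix(0, 6, 6); gb <- matrix(0, 6, 6)
  for (i in 1:6) {
    same <- setdiff(which(labels == labels[i]), i)
    diff <- which(labels != labels[i])
    nw <- same[which.min(D[i, same])]
    nb <- diff[which.min(D[i, diff])]
    gw[i, nw] <- 1; gb[i, nb] <- 1
  }
  gw <- pmax(gw, t(gw)); gb <- pmax(gb, t(gb))
  expect_equal(unclass(a), gw - gb, ignore_attr = TRUE)
  expect_true(all(a %in% c(-1, 0, 1)))
  expect_equal(diag(a), rep(0, 6))
  expect_equal(unclass(a), t(unclass(a)), ignore_attr = TRUE)
})

test_that("affinity validates neighbor counts against class sizes", {
  data <- list(rand_subspace(1, 3, seed = 3), rand_subspace(1, 3, seed = 4))
  expect_error(ng_affinity(data, c(1, 2), nu_w = 1), "too few")
})

test_that("permuting the samples permutes the affinity consistently", {
  mix <- ng_simulate_classes(N_per_class = 4, n = 5, m = 2, p = 1,
                             sigma = 0.1, seed = 5)
  a <- ng_affinity(mix$data, mix$labels, nu_w = 2, nu_b = 2)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  ap <- ng_affinity(mix$data[perm], mix$labels[perm], nu_w = 2, nu_b = 2)
  expect_equal(unclass(ap), unclass(a)[perm, perm], ignore_attr = TRUE)
})

test_that("the supervised loss matches direct evaluation and is O(m)-invariant", {
  set.seed(6)
  data <- lapply(1:4, function(i) rand_subspace(1, 6))
  A <- runif_stiefel(3, 6)
  zero <- matrix(0, 4, 4)
  expect_equal(sng_loss(A, data, zero), 0)
  # a single +1 pair: loss is d^2 / N^2 summed over both orderings
  a <- zero; a[1, 2] <- a[2, 1] <- 1
  pi_ <- function(X) orthonormalize(Conj(t(A)) %*% X)
  expect_equal(sng_loss(A, data, a),
               2 * gr_dist(pi_(data[[1]]), pi_(data[[2]]), "projection")^2 / 16,
               tolerance = 1e-12)
  a[3, 4] <- a[4, 3] <- -1
  O <- runif_stiefel(3, 3)
  expect_equal(sng_loss(A %*% O, data, a), sng_loss(A, data, a), tolerance = 1e-10)
})

test_that("the supervised gradient matches numerical differentiation", {
  for (field in c("real", "complex")) {
    mix <- ng_simulate_classes(N_per_class = 4, n = 6, m = 2, p = 1,
                               sigma = 0.2, field = field, seed = 7)
    aff <- ng_affinity(mix$data, mix$labels, nu_w = 2, nu_b = 2)
    obj <- nestedGrassmann:::make_sup_objective(mix$data, 1, aff, "projection")
    par <- list(A = runif_stiefel(3, 6, field, seed = 8))
    g <- obj$grad(par)
    gn <- nestedGrassmann:::num_grad(par, obj$loss)
    gn$A <- gn$A - par$A %*% (Conj(t(par$A)) %*% gn$A)
    expect_lt(max(Mod(g$A - gn$A)), 1e-6)
  }
})

test_that("supervised reduction improves class separation on a two-component mixture", {
  mix <- ng_simulate_classes(N_per_class = 12, n = 10, m = 3, p = 1,
                             sigma = 0.1, seed = 9)
  fit <- suppressWarnings(sng_fit(mix$data, mix$labels, m = 3, seed = 1))
  expect_equal(fnorm_zero <- max(Mod(fit$B)), 0)       # no offset in L_s
  w <- outer(mix$labels, mix$labels, `==`)
  D0 <- pairwise_dist(mix$data, "projection")
  D1 <- pairwise_dist(lapply(mix$data, function(X) ng_project(fit, X)),
                      "projection")
  ut <- upper.tri(D0)
  margin0 <- mean(D0[!w & ut]) - mean(D0[w & ut])
  margin1 <- mean(D1[!w & ut]) - mean(D1[w & ut])
  expect_gt(margin1, 0)
  expect_gte(margin1, margin0)
  # monotone descent and determinism
  expect_true(all(diff(fit$loss_trace) <= 1e-12))
  fit2 <- suppressWarnings(sng_fit(mix$data, mix$labels, m = 3, seed = 1))
  expect_identical(fit$A, fit2$A)
})

test_that("with a single class the fit collapses projected scatter", {
  sim <- ng_simulate(N = 10, n = 8, m = 3, p = 1, sigma = 0.3, seed = 10)
  labels <- rep(1, 10)
  aff <- ng_affinity(sim$data, labels, nu_w = 3)
  expect_true(all(aff >= 0))                 # no between-class edges exist
  fit <- suppressWarnings(sng_fit(sim$data, labels, m = 3, nu_w = 3, seed = 2))
  set.seed(11)
  rand_losses <- vapply(1:100, function(i)
    sng_loss(runif_stiefel(3, 8), sim$data, aff), numeric(1))
  expect_lte(fit$value, min(rand_losses))
})

test_that("relabeling classes leaves the fitted subspace unchanged", {
  mix <- ng_simulate_classes(N_per_class = 8, n = 8, m = 3, p = 1,
                             sigma = 0.15, seed = 12)
  f1 <- suppressWarnings(sng_fit(mix$data, mix$labels, m = 3, seed = 3))
  f2 <- suppressWarnings(sng_fit(mix$data, 3 - mix$labels, m = 3, seed = 3))
  expect_lt(gr_dist(f1$A, f2$A), 1e-8)
})

test_that("a supervised chain has the same structure as the unsupervised one", {
  mix <- ng_simulate_classes(N_per_class = 8, n = 6, m = 3, p = 1,
                             sigma = 0.15, seed = 13)
  mod <- suppressWarnings(png_fit(mix$data, labels = mix$labels,
                                  nu_w = 3, nu_b = 3))
  expect_true(mod$supervised)
  expect_length(mod$steps, 4)
  expect_equal(ncol(png_scores(mod)), 1 * (6 - 1))
})
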