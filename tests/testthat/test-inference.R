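prior0 <- tismod_prior()
ctrl0 <- tismod_control()

test_that("initialization is deterministic and SVD-aligned", {
  gp <- gp_profile(grid = 6, L = 30, C = 2, seed = 4)
  Yc <- scale(gp$profile$values, scale = FALSE)
  cache <- identity_kernel_cache(nrow(Yc))
  s1 <- tismod:::init_state(Yc, gp$coords, 2, prior0, cache, ctrl0,
                            "random", seed = 99)
  s2 <- tismod:::init_state(Yc, gp$coords, 2, prior0, cache, ctrl0,
                            "random", seed = 99)
  expect_identical(s1, s2)

  # rank-1 noiseless: first map collinear with the true spatial vector
  p <- sin(seq_len(20)); g <- rnorm(8)
  Y1 <- p %*% t(g)
  Y1c <- scale(Y1, scale = FALSE)
  st <- tismod:::init_state(Y1c, cbind(seq_len(20), 1), 1, prior0,
                            identity_kernel_cache(20), ctrl0, "svd", 1)
  # oracle: leading eigenvector of the spot-spot Gram matrix
  ev <- eigen(tcrossprod(Y1c), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(cor(st$mu_P[, 1], ev)), 1, tolerance = 1e-10)

  expect_error(tismod:::init_state(Y1c, cbind(seq_len(20), 1),
                                   min(dim(Y1c)) + 1, prior0,
                                   identity_kernel_cache(20), ctrl0,
                                   "svd", 1),
               "exceeds")
})

test_that("loading and map updates match hand-derived ridge updates", {
  # spike probabilities clamped to 1, identity kernel: the model reduces to
  # Bayesian-ridge alternating updates with known closed forms
  set.seed(8)
  S <- 4; L <- 3
  Y <- matrix(rnorm(S * L), S, L)
  cache <- identity_kernel_cache(S)
  mu0 <- rnorm(S); vd0 <- runif(S, 0.1, 0.3)
  st <- list(C = 1L, S = S, L = L,
             mu_P = matrix(mu0, S, 1), vdiag = matrix(vd0, S, 1),
             Vfull = list(NULL),
             m_om = matrix(0, 1, L), v_om = matrix(1, 1, L),
             w11 = matrix(1, 1, L), w01 = matrix(0, 1, L),
             w00 = matrix(0, 1, L), v0 = 1,
             psi_a = matrix(1, 1, L), psi_b = matrix(1, 1, L),
             rho_a = 1, rho_b = 1,
             lam_a = rep(2, S), lam_b = rep(1, S),
             sig_a = 3, sig_b = 2, bet_a = 1.5, bet_b = 1,
             r_idx = 1L, full_cov = TRUE)
  out <- tismod:::cavi_round(st, Y, cache, prior0, ctrl0,
                             fix_sparsity = TRUE)

  Elam <- rep(2, S); Ebet <- 1.5; Esig <- 1.5
  tau <- Ebet + sum(Elam * (mu0^2 + vd0))
  m_or <- sapply(seq_len(L), function(l) sum(Elam * mu0 * Y[, l]) / tau)
  expect_equal(as.vector(out$m_om), m_or, tolerance = 1e-8)
  expect_equal(as.vector(out$v_om), rep(1 / tau, L), tolerance = 1e-8)

  g2 <- sum(m_or^2 + 1 / tau)
  Lam <- Esig * diag(S) + diag(Elam * g2)
  V <- solve(Lam)
  mu_or <- V %*% (Elam * (Y %*% m_or))
  expect_equal(out$mu_P[, 1], as.vector(mu_or), tolerance = 1e-8)
  expect_equal(out$vdiag[, 1], diag(V), tolerance = 1e-8)
})

test_that("the ELBO is monotone along fits and finite on random states", {
  gp <- gp_profile(grid = 7, L = 50, C = 2, noise_sd = 0.3, seed = 6)
  fit <- tismod(gp$profile, C = 3, seed = 6,
                control = tismod_control(max_iter = 60))
  d <- diff(fit$elbo)
  expect_true(all(d >= -1e-6 * abs(fit$elbo[-length(fit$elbo)])))
  # converged ELBO exceeds the initialization ELBO
  expect_gt(fit$elbo[length(fit$elbo)], fit$elbo[1])

  # finiteness fuzz over seeded random initializations
  Yc <- scale(gp$profile$values, scale = FALSE)
  cache <- identity_kernel_cache(nrow(Yc))
  for (s in 1:25) {
    st <- tismod:::init_state(Yc, gp$coords, 2, prior0, cache, ctrl0,
                              "random", seed = s)
    expect_true(is.finite(tismod:::elbo_state(st, Yc, cache, prior0)))
  }
})

test_that("the ELBO is invariant to a sign flip of a module", {
  gp <- gp_profile(grid = 6, L = 30, seed = 12)
  fit <- tismod(gp$profile, C = 2, seed = 12,
                control = tismod_control(max_iter = 10))
  Yc <- scale(gp$profile$values, scale = FALSE)
  cache <- tismod:::kernel_cache(gp$coords, fit$kernel, keep_inverse = TRUE)
  st <- fit$state
  e1 <- tismod:::elbo_state(st, Yc, cache, fit$prior)
  st$mu_P[, 1] <- -st$mu_P[, 1]
  st$m_om[1, ] <- -st$m_om[1, ]
  e2 <- tismod:::elbo_state(st, Yc, cache, fit$prior)
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-9)
})

test_that("genes without signal are excluded from modules within a few rounds", {
  sim <- simulate_scenario(1, n_genes = 40, grid_size = 8, set_size = 20,
                           seed = 2)
  prof <- sim$profile
  set.seed(2)
  prof$values[, 40] <- rnorm(nrow(prof$values), sd = 1e-6)  # near-zero gene
  fit <- tismod(prof, C = 2, seed = 2,
                control = tismod_control(max_iter = 5))
  expect_lt(fit$pip[1, 40], 0.5)
  expect_lt(fit$pip[2, 40], 0.5)
})

test_that("posterior means reconstruct noiseless low-rank data", {
  gp <- gp_profile(grid = 8, L = 60, C = 2, noise_sd = 0, seed = 21)
  fit <- tismod(gp$profile, C = 3, seed = 21)
  rel <- norm(fitted(fit) - gp$profile$values, "F") /
    norm(gp$profile$values, "F")
  expect_lt(rel, 0.05)
})

test_that("fits are bit-stable under a fixed seed", {
  sim <- simulate_scenario(2, n_genes = 120, grid_size = 8, set_size = 30,
                           seed = 31)
  f1 <- tismod(sim$profile, C = 3, seed = 31,
               control = tismod_control(max_iter = 15))
  f2 <- tismod(sim$profile, C = 3, seed = 31,
               control = tismod_control(max_iter = 15))
  expect_identical(f1$pip, f2$pip)
  expect_identical(f1$maps, f2$maps)
  expect_identical(f1$elbo, f2$elbo)
})

test_that("exact and diagonal map-covariance paths agree on the signal", {
  sim <- simulate_scenario(1, n_genes = 100, grid_size = 8, set_size = 30,
                           seed = 14)
  full <- tismod(sim$profile, C = 2, seed = 14)
  diag_ <- tismod(sim$profile, C = 2, seed = 14,
                  control = tismod_control(full_cov_threshold = 0))
  d <- diff(diag_$elbo)
  expect_true(all(d >= -1e-6 * abs(diag_$elbo[-length(diag_$elbo)])))
  mask <- sim$truth$pattern_fields[[1]]
  a_full <- max(sapply(1:2, function(c)
    tismod:::oriented_auroc(full$maps[, c], mask)["auroc"]))
  a_diag <- max(sapply(1:2, function(c)
    tismod:::oriented_auroc(diag_$maps[, c], mask)["auroc"]))
  expect_gt(a_full, 0.95)
  expect_gt(a_diag, 0.95)
})

test_that("unnormalized input and zero-variance genes are handled", {
  prof <- tiny_count_profile()
  expect_error(tismod(prof, C = 2), "normalized")
  gp <- gp_profile(grid = 5, L = 20, seed = 3)
  gp$profile$values[, 5] <- 2
  expect_warning(fit <- tismod(gp$profile, C = 2, seed = 3,
                               control = tismod_control(max_iter = 5)),
                 "zero variance")
  expect_equal(ncol(fit$loadings), 19L)
})
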