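test_that("AUROC/AUPR match closed forms and a pair-counting oracle", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  res <- auroc_aupr(c(1, 1, 0, 0), lab)
  expect_equal(res$auroc, 1)
  expect_equal(res$aupr, 1)
  # antisymmetry under score negation
  set.seed(4)
  sc <- rnorm(60); lb <- runif(60) < 0.4
  expect_equal(auroc_aupr(-sc, lb)$auroc, 1 - auroc_aupr(sc, lb)$auroc,
               tolerance = 1e-12)
  # midrank tie handling equals explicit pair counting
  sc_t <- sample(round(rnorm(60), 1))
  expect_equal(auroc_aupr(sc_t, lb)$auroc, pair_auroc(sc_t, lb),
               tolerance = 1e-12)
  expect_error(auroc_aupr(sc, rep(TRUE, 60)), "both classes")
})

test_that("random scores on random labels give chance-level AUROC", {
  set.seed(10)
  a <- replicate(20, auroc_aupr(rnorm(1000), runif(1000) < 0.5)$auroc)
  expect_lt(abs(mean(a) - 0.5), 0.05)
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(120); lb <- runif(120) < 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc_aupr(sc, lb)$auroc, ref, tolerance = 1e-10)
})

test_that("threshold-swept ARI matches brute force and is rank invariant", {
  lab <- rep(c(0, 1), each = 25)
  map <- c(rnorm(25, 0), rnorm(25, 3))
  got <- best_threshold_ari(map, lab, n_thresholds = 100)
  # exhaustive oracle over all achievable binarizations
  oracle <- max(sapply(unique(map), function(thr) pair_ari(map > thr, lab)))
  expect_equal(got$ari, oracle, tolerance = 1e-12)
  # ARI at a fixed threshold equals pair counting
  thr <- median(map)
  expect_equal(mclust::adjustedRandIndex(map > thr, lab),
               pair_ari(map > thr, lab), tolerance = 1e-12)
  # perfect binary map
  expect_equal(best_threshold_ari(lab, lab)$ari, 1)
  # strictly monotone transform leaves the best ARI unchanged
  expect_equal(best_threshold_ari(exp(2 * map), lab)$ari, got$ari,
               tolerance = 1e-12)
  # constant map: only the trivial partition is feasible
  expect_equal(best_threshold_ari(rep(2, 50), lab)$ari, 0)
})

test_that("FDR-power curves match prefix counting", {
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  # perfect ranking: full power at zero FDR
  cv <- fdr_power_curve(c(9, 8, 2, 7, 1), truth)
  expect_equal(cv$power[3], 1)
  expect_equal(cv$fdr[3], 0)
  # inverted ranking: no power until FDR is maximal
  ci <- fdr_power_curve(c(1, 2, 9, 3, 8), truth)
  expect_equal(ci$power[2], 0)
  expect_equal(ci$fdr[2], 1)
  # brute-force prefix oracle on a 20-gene fixture
  set.seed(3)
  sc <- rnorm(20); tr <- runif(20) < 0.3
  if (!any(tr)) tr[1] <- TRUE
  cv2 <- fdr_power_curve(sc, tr)
  ord <- order(-sc)
  for (i in c(1, 5, 10, 20)) {
    sel <- ord[seq_len(i)]
    expect_equal(cv2$fdr[i], sum(!tr[sel]) / i)
    expect_equal(cv2$power[i], sum(tr[sel]) / sum(tr))
  }
  expect_error(fdr_power_curve(sc, rep(FALSE, 20)), "true positive")
})

test_that("module-domain alignment matches exhaustive search", {
  set.seed(8)
  S <- 40
  masks <- cbind(d1 = (1:S) <= 15, d2 = (1:S) > 30,
                 d3 = (1:S) > 15 & (1:S) <= 30)
  maps <- cbind(m1 = masks[, 2] + rnorm(S, sd = 0.3),
                m2 = -(masks[, 1] + rnorm(S, sd = 0.3)),  # flipped
                m3 = masks[, 3] + rnorm(S, sd = 0.3))
  one <- align_to_domains(maps, masks, mode = "one_to_one")
  # oracle: brute force over all 6 permutations of an independently
  # computed orientation-aware score matrix
  score <- matrix(0, 3, 3)
  for (c in 1:3) for (d in 1:3) {
    a <- pair_auroc(maps[, c], masks[, d])
    score[c, d] <- max(a, 1 - a)
  }
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  best <- max(sapply(perms, function(p) mean(score[cbind(1:3, p)])))
  expect_equal(one$mean_auroc, best, tolerance = 1e-12)
  # the flipped module is matched with negative orientation
  ali <- one$alignment
  expect_equal(ali$orientation[ali$module == "m2"], -1)

  bpd <- align_to_domains(maps, masks, mode = "best_per_domain")
  # relaxation ordering: one-to-one mean cannot exceed per-domain best mean
  expect_lte(one$mean_auroc, bpd$mean_auroc + 1e-12)
  # a module equal to a domain mask aligns with AUROC 1
  maps2 <- cbind(as.numeric(masks[, 1]))
  a1 <- align_to_domains(maps2, masks[, 1, drop = FALSE])
  expect_equal(a1$alignment$auroc, 1)
  expect_equal(a1$alignment$module, "module1")
})

test_that("the assignment solver equals exhaustive search beyond 3x3", {
  set.seed(13)
  for (n in c(5, 7)) {
    sc <- matrix(runif(n * n), n, n)
    perms <- tismod:::permutations_of(n)
    vals <- apply(perms, 1, function(p) sum(sc[cbind(1:n, p)]))
    best <- max(vals)
    hung <- tismod:::hungarian_max(sc)
    expect_equal(sum(sc[cbind(1:n, hung)]), best, tolerance = 1e-10)
  }
})

test_that("alignment warns when modules are fewer than domains", {
  set.seed(2)
  maps <- matrix(rnorm(30), ncol = 1)
  masks <- cbind((1:30) < 10, (1:30) >= 20)
  expect_warning(res <- align_to_domains(maps, masks, "one_to_one"),
                 "unmatched")
  expect_equal(nrow(res$alignment), 1L)
})

test_that("metrics are invariant to a joint permutation of spots", {
  set.seed(12)
  map <- rnorm(40); lab <- runif(40) < 0.4
  if (!any(lab)) lab[1] <- TRUE
  if (all(lab)) lab[2] <- FALSE
  perm <- sample(40)
  expect_equal(auroc_aupr(map[perm], lab[perm]), auroc_aupr(map, lab))
  expect_equal(best_threshold_ari(map[perm], lab[perm])$ari,
               best_threshold_ari(map, lab)$ari)
})
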