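fake_modules <- function() {
  pip <- rbind(c(0.9, 0.5, 0.6, 0.2, 0.95),
               c(0.1, 0.8, 0.4, 0.85, 0.3))
  load <- rbind(c(2.0, 1.0, -1.5, 0.3, 0.5),
                c(-0.2, -2.5, 0.8, 1.2, -0.1))
  genes <- paste0("g", 1:5)
  colnames(pip) <- colnames(load) <- genes
  rownames(pip) <- rownames(load) <- c("module1", "module2")
  list(pip = pip, loadings = load, gene_names = genes)
}

test_that("membership uses a strict PIP threshold", {
  m <- fake_modules()
  memb <- gene_membership(m)
  expect_true(memb[1, 1])
  expect_false(memb[1, 2])       # exactly 0.5 is not membership
  expect_true(memb[1, 3])
  # threshold 1 empties membership when all pips < 1
  expect_false(any(gene_membership(m, threshold = 1)))
  # counts equal an independent recount
  expect_equal(rowSums(memb), apply(m$pip, 1, function(p) sum(p > 0.5)))
  expect_error(gene_membership(m, threshold = 1.2), "probability")
})

test_that("z-scored maps have zero mean, unit variance, affine invariance", {
  set.seed(5)
  x <- rnorm(50, mean = 3, sd = 7)
  z <- scale_map(x, "zscore")
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::var(z) - 1), 1e-12)
  expect_equal(scale_map(2.5 * x + 4, "zscore"), z, tolerance = 1e-12)
  # idempotent
  expect_equal(scale_map(z, "zscore"), z, tolerance = 1e-12)
  expect_error(scale_map(rep(1, 10), "zscore"), "constant")
})

test_that("signed log scaling preserves signs", {
  x <- c(-3, -0.5, 0, 0.2, 5)
  s <- scale_map(x, "signed_log")
  expect_equal(sign(s), sign(x))
  expect_lt(s[5], x[5])          # compresses large activities
})

test_that("top_genes ranks member genes by absolute loading", {
  m <- fake_modules()
  # module 1 members: g1 (2.0), g3 (-1.5), g5 (0.5)
  expect_equal(top_genes(m, 1, k = 10, direction = "positive"),
               c("g1", "g5"))
  expect_equal(top_genes(m, 1, k = 1, direction = "positive"), "g1")
  expect_equal(top_genes(m, 1, k = 10, direction = "negative"), "g3")
  # brute-force oracle on a random module
  set.seed(9)
  pip <- matrix(runif(40), 1); load <- matrix(rnorm(40), 1)
  genes <- sprintf("g%02d", 1:40)
  colnames(pip) <- colnames(load) <- genes
  mm <- list(pip = pip, loadings = load, gene_names = genes)
  keep <- pip[1, ] > 0.5 & load[1, ] > 0
  oracle <- genes[keep][order(-abs(load[1, keep]), genes[keep])]
  expect_equal(top_genes(mm, 1, k = 100, direction = "positive"), oracle)
  # sign symmetry: flipped module, opposite direction, same list
  mflip <- mm; mflip$loadings <- -mflip$loadings
  expect_equal(top_genes(mflip, 1, k = 100, direction = "negative"), oracle)
  expect_warning(res <- top_genes(mm, 1, k = 5, direction = "negative"),
                 NA)
})

test_that("hypergeometric overlap matches direct pmf summation", {
  bg <- sprintf("g%04d", 1:2000)
  # exact log-pmf summation oracle
  tail_oracle <- function(ov, nA, nB, N) {
    ks <- ov:min(nA, nB)
    sum(exp(lchoose(nA, ks) + lchoose(N - nA, nB - ks) - lchoose(N, nB)))
  }
  set.seed(1)
  for (case in list(c(50, 50, 0), c(50, 50, 5), c(30, 80, 12),
                    c(10, 10, 10))) {
    nA <- case[1]; nB <- case[2]; ov <- case[3]
    a <- bg[seq_len(nA)]
    b <- c(a[seq_len(ov)],
           bg[seq(nA + 1, length.out = nB - ov)])
    res <- compare_modules(a, b, bg)
    expect_equal(res$overlap, ov)
    expect_equal(res$p_value, tail_oracle(ov, nA, nB, 2000),
                 tolerance = 1e-12)
  }
  # identical sets attain the minimal possible p for those sizes
  a <- bg[1:50]
  res <- compare_modules(a, a, bg)
  expect_equal(res$overlap, 50)
  expect_equal(res$p_value, tail_oracle(50, 50, 50, 2000), tolerance = 1e-15)
  expect_error(compare_modules(c(a, "unknown"), a, bg), "background")
})

test_that("overlap p-value decreases as the overlap grows", {
  bg <- sprintf("g%03d", 1:200)
  ps <- sapply(0:20, function(ov) {
    a <- bg[1:20]
    b <- c(a[seq_len(ov)], bg[seq(21, length.out = 20 - ov)])
    compare_modules(a, b, bg)$p_value
  })
  expect_true(all(diff(ps) < 0))
})
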