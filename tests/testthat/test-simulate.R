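test_that("scenario profiles have the declared shape and truth structure", {
  sim <- simulate_scenario(1, seed = 5)
  expect_equal(dim(sim$profile), c(256L, 1000L))
  expect_length(sim$truth$pattern_fields, 1L)
  mask <- sim$truth$pattern_fields[[1]]
  expect_true(any(mask) && !all(mask))      # strictly inside the grid
  expect_equal(sum(lengths(sim$truth$memberships) > 0), 100L)

  # scenario 4: disjoint genes and patterns; scenario 5: overlapping genes
  s4 <- simulate_scenario(4, n_genes = 300, grid_size = 10, set_size = 50,
                          seed = 6)
  in4 <- sapply(s4$truth$memberships, length)
  expect_equal(sum(in4 == 2), 0L)
  expect_false(any(s4$truth$pattern_fields[[1]] &
                   s4$truth$pattern_fields[[2]]))
  s5 <- simulate_scenario(5, n_genes = 300, grid_size = 10, set_size = 50,
                          overlap_frac = 0.2, seed = 6)
  in5 <- sapply(s5$truth$memberships, length)
  expect_equal(sum(in5 == 2), 10L)          # 20% of 50 genes shared
})

test_that("multi-scale scenarios produce strictly nested masks", {
  for (scn in 6:7) {
    sim <- simulate_scenario(scn, n_genes = 400, grid_size = 12,
                             set_size = 60, seed = scn)
    masks <- sim$truth$pattern_fields
    expect_length(masks, scn - 4L)
    for (k in seq_len(length(masks) - 1)) {
      expect_true(all(masks[[k + 1]] <= masks[[k]]))  # nested
      expect_lt(sum(masks[[k + 1]]), sum(masks[[k]])) # strictly
      expect_gt(sum(masks[[k + 1]]), 0)
    }
  }
})

test_that("simulation output is seed-deterministic and validated", {
  a <- simulate_scenario(3, n_genes = 50, grid_size = 8, set_size = 10,
                         seed = 7)
  b <- simulate_scenario(3, n_genes = 50, grid_size = 8, set_size = 10,
                         seed = 7)
  expect_identical(a$profile$values, b$profile$values)
  expect_identical(a$truth, b$truth)
  cnt <- simulate_scenario(1, n_genes = 30, grid_size = 6, set_size = 10,
                           counts = TRUE, seed = 1)
  expect_true(all(cnt$profile$values >= 0))
  expect_true(all(cnt$profile$values == round(cnt$profile$values)))
  expect_false(cnt$profile$is_normalized)
  expect_error(simulate_scenario(9), "1..7")
  expect_error(simulate_scenario(1, grid_size = 3), "grid_size")
  expect_error(simulate_scenario(5, overlap_frac = 1.5), "overlap_frac")
})

test_that("a zero effect leaves spatial genes indistinguishable from noise", {
  aucs <- sapply(1:20, function(s) {
    sim <- simulate_scenario(1, n_genes = 60, grid_size = 8, set_size = 20,
                             effect = 0, seed = s)
    mask <- sim$truth$pattern_fields[[1]]
    member <- lengths(sim$truth$memberships) > 0
    score <- rowMeans(sim$profile$values[, member])
    auroc_aupr(score, mask)$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("layered geometries form contiguous non-empty bands", {
  geo <- make_layered_geometry()
  expect_equal(nrow(geo$coords), 3611L)
  expect_equal(sort(unique(geo$layers)), 1:7)
  sizes <- tabulate(geo$layers, 7)
  expect_true(all(sizes > 0))
  # equal widths: sizes within one lattice row of n/7
  ncols <- ceiling(sqrt(3611))
  expect_true(all(abs(sizes - 3611 / 7) <= ncols))
  # bands are contiguous in y
  for (k in 1:7) {
    ys <- sort(unique(geo$coords[geo$layers == k, 2]))
    all_ys <- sort(unique(geo$coords[, 2]))
    expect_equal(ys, all_ys[all_ys >= min(ys) & all_ys <= max(ys)])
  }

  # exact small case: 16 spots, 2 layers on a square lattice
  g2 <- make_layered_geometry(16, 2, lattice = "square")
  expect_equal(tabulate(g2$layers, 2), c(8L, 8L))
  expect_error(make_layered_geometry(5, 7), "n_spots")
})

test_that("layered NB profiles carry the stated truth and moments", {
  geo <- make_layered_geometry(600, 4, lattice = "square")
  sim <- simulate_layered(geo, target_layer = 2, n_spatial = 30,
                          n_noise = 70, mu_in = 5, mu_out = 1,
                          dispersion = 0.5, seed = 3)
  expect_equal(ncol(sim$profile$values), 100L)
  expect_length(sim$truth$spatial_genes, 30L)
  expect_equal(sim$truth$mask, geo$layers == 2)
  # moment check: empirical in-layer mean within 3 SE of mu_in
  n_in <- sum(sim$truth$mask)
  se <- sqrt((5 + 5^2 / 0.5) / n_in)
  g1 <- sim$profile$values[sim$truth$mask, 1]
  expect_lt(abs(mean(g1) - 5), 3 * se)
  expect_true(all(sim$profile$values == round(sim$profile$values)))
  expect_error(simulate_layered(geo, target_layer = 9), "layer")
  expect_error(simulate_layered(geo, 1, mu_in = 1, mu_out = 2), "mu_in")
})

test_that("equal NB means give no layer signal", {
  geo <- make_layered_geometry(400, 4, lattice = "square")
  aucs <- sapply(1:20, function(s) {
    sim <- simulate_layered(geo, 2, n_spatial = 20, n_noise = 30,
                            mu_in = 2, mu_out = 2, seed = s)
    # per-gene layer-vs-rest rank statistic, averaged over spatial genes
    mean(sapply(1:20, function(l)
      auroc_aupr(sim$profile$values[, l], sim$truth$mask)$auroc))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
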