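make_planted_vols <- function(n_subjects = 4L, n_scans = 120L, seed = 1L,
                              snr = Inf, gains = NULL) {
  grid <- c(12L, 12L, 6L)
  maps <- make_network_maps(grid)
  mask <- array(TRUE, grid)
  m_lin <- which(mask)
  M <- cbind(maps$early[m_lin], maps$transition[m_lin])
  gains <- gains %||% rep(1, n_subjects)
  withr::with_seed(seed, {
    vols <- lapply(seq_len(n_subjects), function(i) {
      tc <- matrix(rnorm(n_scans * 2L), n_scans)
      dat <- gains[i] * tc %*% t(M)
      if (is.finite(snr)) dat <- dat + matrix(rnorm(length(dat), sd = 1 / snr),
                                              nrow = n_scans)
      volume_series(dat, mask, 2, subject_id = sprintf("S%02d", i),
                    group = if (i <= n_subjects / 2) "musician" else "nonmusician")
    })
  })
  list(vols = vols, M = M, mask = mask)
}

test_that("two-step reduction is lossless at full rank and reports retained variance", {
  pl <- make_planted_vols(3L, 60L, seed = 2L)
  # every subject shares the same two spatial sources, so the stacked data
  # have rank 2 as well
  red <- reduce_two_step(pl$vols, subject_dim = 2L, group_dim = 2L)
  # data have exact rank 2 per subject: reconstruction through the retained
  # basis is lossless
  for (i in 1:3) {
    X <- sweep(pl$vols[[i]]$data, 2, colMeans(pl$vols[[i]]$data))
    U <- red$subjects[[i]]$U
    expect_lt(max(abs(U %*% crossprod(U, X) - X)), 1e-8)
  }
  # white-noise data: retained variance fraction equals the eigenvalue ratio
  withr::with_seed(5, {
    nvols <- lapply(1:2, function(i)
      volume_series(matrix(rnorm(40 * 100), 40), array(TRUE, c(10L, 10L, 1L)), 2))
  })
  red2 <- reduce_two_step(nvols, 10L, 8L)
  Y <- red2$Y
  ev <- svd(Y)$d^2
  retained <- sum(crossprod(red2$G, Y)^2) / sum(Y^2)
  expect_equal(retained, sum(ev[1:8]) / sum(ev), tolerance = 1e-10)
  # scale invariance of the subspaces
  dbl <- lapply(pl$vols, function(v) { v$data <- 2 * v$data; v })
  red3 <- reduce_two_step(dbl, 2L, 2L)
  for (i in 1:3) {
    cc <- abs(cor(red$subjects[[i]]$U, red3$subjects[[i]]$U))
    expect_equal(sort(apply(cc, 1, max)), c(1, 1), tolerance = 1e-8)
  }
  expect_error(reduce_two_step(pl$vols, 50L, 4L), "rank|exceeds")
  expect_error(reduce_two_step(pl$vols, 2L, 40L), "exceeds")
})

test_that("spatial ICA recovers planted disjoint sources and is deterministic", {
  pl <- make_planted_vols(4L, 120L, seed = 3L, snr = 100)
  red <- reduce_two_step(pl$vols, 10L, 6L)
  dec <- fit_spatial_ica(red, 2L, seed = 9L)
  mc <- match_components(t(pl$M), dec$group_maps, threshold = 0.5)
  expect_equal(nrow(mc), 2L)
  expect_true(all(mc$abs_cor >= 0.99))
  # determinism: bit-for-bit identical refit
  dec2 <- fit_spatial_ica(red, 2L, seed = 9L)
  expect_identical(dec$group_maps, dec2$group_maps)
  expect_identical(dec$mixing, dec2$mixing)
  # spatial decorrelation of the group maps
  cc <- cor(t(dec$group_maps))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  # sign convention: peak-magnitude voxel positive
  for (c in 1:2) {
    v <- dec$group_maps[c, ]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(fit_spatial_ica(red, 10L, seed = 1L), "exceeds")
})

test_that("single-source data yield the source at model order one", {
  grid <- c(10L, 10L, 4L)
  maps <- make_network_maps(grid)
  mask <- array(TRUE, grid)
  src <- maps$early[which(mask)]
  withr::with_seed(11, {
    vols <- lapply(1:3, function(i)
      volume_series(matrix(rnorm(50), 50) %*% t(src) +
                      matrix(rnorm(50 * length(src), sd = 1e-3), 50),
                    mask, 2))
  })
  red <- reduce_two_step(vols, 3L, 3L)
  dec <- fit_spatial_ica(red, 1L, seed = 2L)
  expect_gt(abs(cor(dec$group_maps[1, ], src)), 0.99)
})

test_that("GICA3 back-reconstruction satisfies its consistency property", {
  pl <- make_planted_vols(5L, 80L, seed = 7L, snr = 5)
  red <- reduce_two_step(pl$vols, 8L, 6L)
  for (k in c(2L, 4L, 6L)) {
    dec <- fit_spatial_ica(red, k, seed = 4L)
    back <- back_reconstruct_gica3(dec, red)
    avg <- Reduce(`+`, back$subject_maps) / length(back$subject_maps)
    relerr <- max(abs(avg - dec$group_maps)) / max(abs(dec$group_maps))
    expect_lt(relerr, 1e-6)
    expect_equal(nrow(back$timecourses[[1]]), 80L)
  }
  # single subject: subject map equals the group map
  red1 <- reduce_two_step(pl$vols[1], 8L, 6L)
  dec1 <- fit_spatial_ica(red1, 2L, seed = 4L)
  back1 <- back_reconstruct_gica3(dec1, red1)
  expect_lt(max(abs(back1$subject_maps[[1]] - dec1$group_maps)), 1e-8)
  # planted subject gains are recovered in rank order
  pl2 <- make_planted_vols(4L, 150L, seed = 13L, snr = 10,
                           gains = c(1, 1, 1.5, 1.5))
  red2 <- reduce_two_step(pl2$vols, 6L, 5L)
  dec2 <- fit_spatial_ica(red2, 2L, seed = 6L)
  back2 <- back_reconstruct_gica3(dec2, red2)
  amp <- vapply(back2$subject_maps, function(m) sd(m[1, ]), 0)
  expect_true(mean(amp[3:4]) > mean(amp[1:2]))
})

test_that("model-order scanning matches planted components across orders", {
  pl <- make_planted_vols(4L, 120L, seed = 17L, snr = 3)
  red <- reduce_two_step(pl$vols, 10L, 8L)
  sc <- scan_model_orders(red, c(2L, 3L, 4L), seed = 3L)
  expect_equal(sc$reference_order, 4L)
  ref <- sc$fits[["4"]]$group_maps
  planted_idx <- match_components(t(pl$M), ref, 0.7)
  expect_equal(nrow(planted_idx), 2L)
  expect_true(all(sc$stability[planted_idx$b] >= 0.9, na.rm = TRUE))
  # single order reduces to one fit
  sc1 <- scan_model_orders(red, 3L, seed = 3L)
  expect_length(sc1$fits, 1L)
  expect_identical(sc1$fits[["3"]]$group_maps,
                   fit_spatial_ica(red, 3L, seed = derive_seed(3L, 13L))$group_maps)
})

test_that("lag profiling classifies constructed components correctly", {
  n <- 100
  set.seed(23)
  reg <- abs(rnorm(n)) + (0:(n - 1) %% 11 == 0) * 4
  X <- build_lag_design(reg, c(-1L, 0L, 1L), tr = 2)
  lagged <- X[, -1]
  # every subject's first component tracks the lag -1 regressor
  tcs <- lapply(1:8, function(i)
    cbind(lagged[, 1] + rnorm(n, sd = 0.1), rnorm(n)))
  prof <- profile_lag_significance(tcs, lagged, c(-1L, 0L, 1L), alpha = 0.05)
  expect_equal(prof$classification[1], "early")
  expect_equal(prof$classification[2], "unrelated")
  expect_equal(which.min(prof$table$p[prof$table$component == 1]), 1L)
  # white-noise components rarely reach a strict alpha
  set.seed(31)
  hits <- 0L
  for (r in 1:40) {
    tcs0 <- lapply(1:8, function(i) cbind(rnorm(n)))
    p0 <- profile_lag_significance(tcs0, lagged, c(-1L, 0L, 1L), alpha = 0.01)
    if (p0$classification[1] != "unrelated") hits <- hits + 1L
  }
  expect_lte(hits / 40, 3 * 0.01 + 2 * sqrt(0.03 * 0.97 / 40) + 0.05)
})

test_that("ICA group-map comparison flips sign with the labels and detects planted gain", {
  pl <- make_planted_vols(8L, 100L, seed = 29L, snr = 3,
                          gains = c(rep(1.8, 4), rep(1, 4)))
  red <- reduce_two_step(pl$vols, 8L, 6L)
  dec <- fit_spatial_ica(red, 2L, seed = 8L)
  back <- back_reconstruct_gica3(dec, red)
  groups <- rep(c("musician", "nonmusician"), each = 4)
  cc <- compare_groups_ica(back$subject_maps, groups, pl$mask, component = 1L,
                           forming_p = 0.05, n_permutations = 200, seed = 3L)
  cc_swap <- compare_groups_ica(back$subject_maps, rev(groups), pl$mask,
                                component = 1L, forming_p = 0.05,
                                n_permutations = 200, seed = 3L)
  expect_equal(cc$stat, -cc_swap$stat, tolerance = 1e-12)
  expect_error(compare_groups_ica(back$subject_maps, rep("m", 8), pl$mask),
               "two groups")
})
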