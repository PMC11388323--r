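make_vol <- function(data, tr = 2) {
  mask <- array(TRUE, dim = c(ncol(data), 1L, 1L))
  volume_series(data, mask, tr)
}

test_that("confound removal leaves residuals exactly orthogonal to the confound", {
  set.seed(3)
  conf <- rnorm(40)
  # a voxel equal to the confound vanishes; an orthogonal zero-mean voxel survives
  orth <- rnorm(40)
  orth <- orth - mean(orth)
  orth <- orth - conf * sum(orth * (conf - mean(conf))) / sum((conf - mean(conf))^2)
  orth <- orth - mean(orth)
  vol <- make_vol(cbind(conf, orth, rnorm(40)))
  res <- regress_out_confound(vol, conf)
  expect_lt(max(abs(res$data[, 1])), 1e-10)
  expect_lt(max(abs(res$data[, 2] - orth)), 1e-10)
  expect_lt(max(abs(cor(res$data, conf))), 1e-10)
  # closed-form oracle on a tiny series
  y <- c(1, 2, 3, 5); x <- c(1, 2, 3, 4)
  r4 <- regress_out_confound(make_vol(matrix(y, 4)), x)$data[, 1]
  beta <- ols_oracle(cbind(1, x), y)
  expect_equal(r4, y - cbind(1, x) %*% beta, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(regress_out_confound(vol, rep(1, 40)), "constant")
})

test_that("the lagged GLM recovers noise-free betas exactly", {
  set.seed(8)
  reg <- abs(rnorm(60)) + (0:59 %% 7 == 0) * 3
  X <- build_lag_design(reg, c(-1L, 0L, 1L), tr = 2, convolve = FALSE)
  truevox <- 2 * X[, "lag_0"]
  vol <- make_vol(cbind(truevox, rnorm(60), 5 + 0.5 * X[, "lag_-1"]))
  fit <- fit_subject_glm(vol, X)
  expect_equal(unname(fit$betas[1, "lag_0"]), 2, tolerance = 1e-10)
  expect_lt(abs(fit$betas[1, "lag_-1"]), 1e-10)
  expect_lt(abs(fit$betas[1, "lag_1"]), 1e-10)
  expect_equal(unname(fit$betas[3, "lag_-1"]), 0.5, tolerance = 1e-10)
  expect_equal(fit$dof, 60 - 4)
  # one-sided p pairs sum to one
  expect_equal(fit$p_pos + fit$p_neg, matrix(1, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("GLM betas and t statistics match the matrix-algebra oracle", {
  set.seed(21)
  reg <- rnorm(30)
  X <- build_lag_design(reg, c(-1L, 0L, 1L), tr = 2, convolve = FALSE)
  Y <- matrix(rnorm(90), 30)
  fit <- fit_subject_glm(make_vol(Y), X)
  for (v in 1:3) {
    beta <- ols_oracle(X, Y[, v])
    expect_equal(unname(fit$betas[v, ]), unname(beta[2:4, 1]),
                 tolerance = 1e-10)
    res <- Y[, v] - X %*% beta
    s2 <- sum(res^2) / (30 - 4)
    se <- sqrt(diag(solve(t(X) %*% X)) * s2)
    expect_equal(unname(fit$t_stats[v, ]), unname(beta[2:4, 1] / se[2:4]),
                 tolerance = 1e-10)
  }
  # per-lag mode fits each lag separately
  fit1 <- fit_subject_glm(make_vol(Y), X, joint = FALSE)
  b_or <- ols_oracle(X[, c(1, 2)], Y[, 1])[2]
  expect_equal(unname(fit1$betas[1, "lag_-1"]), unname(b_or), tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  reg <- rnorm(30)
  X <- build_lag_design(reg, c(0L, 0L), tr = 2, convolve = FALSE)
  expect_error(fit_subject_glm(make_vol(matrix(rnorm(30))), X), "lag_0")
})

test_that("GLM type-I error is calibrated on pure noise", {
  set.seed(99)
  reg <- rnorm(100)
  X <- build_lag_design(reg, c(-1L, 0L, 1L), tr = 2, convolve = FALSE)
  Y <- matrix(rnorm(100 * 1000), 100)
  fit <- fit_subject_glm(make_vol(Y), X)
  p_two <- 2 * pmin(fit$p_pos[, "lag_0"], fit$p_neg[, "lag_0"])
  rate <- mean(p_two < 0.05)
  expect_gte(rate, qbinom(0.005, 1000, 0.05) / 1000)
  expect_lte(rate, qbinom(0.995, 1000, 0.05) / 1000)
})

test_that("Fisher pooling matches the chi-square closed form", {
  expect_warning(z <- fisher_combine(matrix(c(1, 0), 2, 1)), "clipped")
  one <- fisher_combine(matrix(1, 3, 2))
  expect_equal(one$stat, c(0, 0))
  expect_equal(one$p, c(1, 1))
  # single-subject identity
  p <- matrix(c(0.2, 0.7), 1, 2)
  expect_equal(fisher_combine(p)$p, c(0.2, 0.7), tolerance = 1e-9)
  # closed-form oracle for p = {0.05, 0.10}
  two <- fisher_combine(matrix(c(0.05, 0.10), 2, 1))
  stat_or <- -2 * (log(0.05) + log(0.10))
  expect_equal(two$stat, stat_or, tolerance = 1e-9)
  expect_equal(two$p, pchisq(stat_or, 4, lower.tail = FALSE), tolerance = 1e-9)
  expect_error(fisher_combine(matrix(c(0.5, 1.2), 2, 1)), "lie in")
})

test_that("lag comparisons give exact rank-sum p-values and nulls", {
  A <- matrix(rep(1:5, 3), 5)
  same <- compare_lags(list(lag_a = A, lag_b = A))
  expect_true(all(same[[1]]$p == 1))
  # complete separation at n = 5 + 5: two-sided p = 2 / choose(10, 5)
  B <- A + 10
  sep <- compare_lags(list(lag_a = B, lag_b = A))
  expect_equal(unique(sep[[1]]$p), 2 / choose(10, 5), tolerance = 1e-12)
  oracle <- rank_sum_oracle(B[, 1], A[, 1])
  expect_equal(unique(sep[[1]]$p), oracle$p_two, tolerance = 1e-12)
  # paired signed-rank variant (distinct positive shifts keep the null exact)
  B2 <- A + matrix(seq(5, 9), 5, 3)
  sr <- compare_lags(list(lag_a = B2, lag_b = A), method = "signed_rank")
  expect_equal(unique(sr[[1]]$p), 2 / 2^5, tolerance = 1e-12)
})

test_that("group comparison is calibrated, antisymmetric, and sensitive to planted gain", {
  set.seed(12)
  maps <- matrix(rnorm(16 * 200), 16)
  groups <- rep(c("musician", "nonmusician"), each = 8)
  null <- compare_groups_glm(maps, groups)
  rate <- mean(null$p < 0.05)
  expect_lte(rate, qbinom(0.9995, 200, 0.05) / 200)
  flipped <- compare_groups_glm(maps, rev(groups))
  expect_equal(null$z, -flipped$z, tolerance = 1e-12)
  # planted group effect in the first 50 voxels
  maps2 <- maps
  maps2[1:8, 1:50] <- maps2[1:8, 1:50] + 2
  eff <- compare_groups_glm(maps2, groups)
  expect_gt(mean(eff$p[1:50] < 0.05), mean(eff$p[51:200] < 0.05))
  expect_error(compare_groups_glm(maps, rep("g1", 16)), "two groups")
})

test_that("Spearman association is rank-invariant and matches enumeration at tiny n", {
  set.seed(5)
  reg <- rnorm(20)
  vol <- make_vol(cbind(reg, exp(reg), rnorm(20)))
  sa <- spearman_association(vol, reg)
  expect_equal(sa$rho[1], 1)
  expect_equal(sa$rho[2], 1)  # monotone transform
  # n = 4: exact permutation p
  r4 <- c(0.3, -1, 0.5, 2)
  v4 <- make_vol(matrix(c(0.3, -0.2, 0.4, 1.9), 4))
  sa4 <- spearman_association(v4, r4)
  expect_equal(sa4$rho[1], cor(rank(c(0.3, -0.2, 0.4, 1.9)), rank(r4)))
  perms <- eventseg:::permutations_all(4)
  null_rho <- apply(perms, 1, function(pp) cor(1:4, (1:4)[pp]))
  expect_equal(sa4$p[1], mean(abs(null_rho) >= abs(sa4$rho[1]) - 1e-12))
  # constant voxel flagged
  vc <- make_vol(cbind(rep(1, 20), reg))
  sac <- spearman_association(vc, reg)
  expect_true(is.na(sac$rho[1]))
})
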