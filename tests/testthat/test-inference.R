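test_that("signed-rank p-values match exhaustive enumeration for n <= 8", {
  set.seed(31)
  for (n in 2:8) {
    for (rep in 1:6) {
      x <- round(rnorm(n), 3)
      if (any(x == 0) || anyDuplicated(abs(x))) next
      got <- wilcoxon_signed_rank(x)
      oracle <- signed_rank_oracle(x)
      expect_identical(got$exact, TRUE)
      expect_equal(got$statistic, oracle$statistic)
      expect_equal(got$p_greater, oracle$p_greater, tolerance = 1e-12)
      expect_equal(got$p_less, oracle$p_less, tolerance = 1e-12)
      expect_equal(got$p_two, oracle$p_two, tolerance = 1e-12)
    }
  }
  # all positive shifts at n = 5: one-sided tail 1/32
  allpos <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(allpos$p_greater, 1 / 32, tolerance = 1e-12)
  # symmetric values sit at the null centre
  sym <- wilcoxon_signed_rank(c(-2, -1, 1, 2))
  expect_equal(sym$p_two, 1)
  expect_equal(wilcoxon_signed_rank(rep(0, 4))$p_two, 1)
})

test_that("rank-sum p-values match exhaustive enumeration for n <= 8", {
  set.seed(77)
  for (n1 in 2:4) {
    for (n2 in 2:4) {
      x <- rnorm(n1); y <- rnorm(n2)
      got <- wilcoxon_rank_sum(x, y)
      oracle <- rank_sum_oracle(x, y)
      expect_identical(got$exact, TRUE)
      expect_equal(got$statistic, oracle$statistic)
      expect_equal(got$p_greater, oracle$p_greater, tolerance = 1e-12)
      expect_equal(got$p_two, oracle$p_two, tolerance = 1e-12)
    }
  }
  # ties fall back to the midrank normal approximation
  tied <- wilcoxon_rank_sum(c(1, 2, 2), c(2, 3, 4))
  expect_identical(tied$exact, FALSE)
})

test_that("FDR adjustment applies the step-up rule and preserves order", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in the ranks
  expect_error(fdr_adjust(c(0.5, 1.2)), "lie in")
})

test_that("connected-component labelling respects 26- and 6-connectivity", {
  dim3 <- c(6L, 6L, 4L)
  arr <- array(FALSE, dim3)
  arr[1:2, 1:2, 1] <- TRUE          # block of 4
  arr[5:6, 5:6, 3] <- TRUE          # separate block of 4
  labs <- eventseg:::label_clusters(which(arr), dim3, 26L)
  expect_equal(length(unique(labs)), 2L)
  expect_equal(sort(table(labs)), sort(table(c(1, 1, 1, 1, 2, 2, 2, 2))),
               ignore_attr = TRUE)
  # diagonal touch merges under 26- but not 6-connectivity
  arr2 <- array(FALSE, dim3)
  arr2[2, 2, 2] <- TRUE
  arr2[3, 3, 3] <- TRUE
  expect_equal(length(unique(eventseg:::label_clusters(which(arr2), dim3, 26L))), 1L)
  expect_equal(length(unique(eventseg:::label_clusters(which(arr2), dim3, 6L))), 2L)
})

test_that("cluster correction returns empty tables on null or over-thresholded maps", {
  mask <- array(TRUE, c(8L, 8L, 4L))
  zero <- matrix(0, 10, 256)
  cc <- cluster_correct(zero, mask, 0.001, "sign_flip", n_permutations = 100,
                        seed = 2)
  expect_equal(nrow(cc$table), 0L)
  set.seed(6)
  noise <- matrix(rnorm(10 * 256), 10)
  cc2 <- cluster_correct(noise, mask, 1e-12, "sign_flip",
                         n_permutations = 100, seed = 2)
  expect_equal(nrow(cc2$table), 0L)
  expect_warning(cluster_correct(noise, mask, 0.001, "sign_flip",
                                 n_permutations = 50, seed = 2), "coarse")
})

test_that("a planted blob survives sign-flip cluster correction", {
  mask <- array(TRUE, c(12L, 12L, 6L))
  blob <- array(FALSE, dim(mask))
  blob[5:8, 5:8, 3:4] <- TRUE
  set.seed(10)
  maps <- matrix(rnorm(12 * sum(mask)), 12)
  maps[, blob[mask]] <- maps[, blob[mask]] + 2
  cc <- cluster_correct(maps, mask, 0.001, "sign_flip", n_permutations = 300,
                        seed = 5)
  expect_gte(nrow(cc$table), 1L)
  expect_lt(cc$table$corrected_p[1], 0.05)
  expect_gte(cc$table$extent[1], 16L)
  expect_equal(cc$table$sign[1], 1)
})

test_that("label-shuffle cluster correction finds planted group differences", {
  mask <- array(TRUE, c(10L, 10L, 5L))
  blob <- array(FALSE, dim(mask)); blob[4:7, 4:7, 2:4] <- TRUE
  set.seed(3)
  maps <- matrix(rnorm(20 * sum(mask)), 20)
  groups <- rep(c("a", "b"), each = 10)
  maps[groups == "a", blob[mask]] <- maps[groups == "a", blob[mask]] + 2.5
  cc <- cluster_correct(maps, mask, 0.01, "label_shuffle", groups = groups,
                        n_permutations = 300, seed = 8)
  expect_gte(nrow(cc$table), 1L)
  expect_lt(cc$table$corrected_p[1], 0.05)
  expect_error(cluster_correct(maps, mask, 0.01, "label_shuffle",
                               n_permutations = 100), "group labels")
})

test_that("lag-map clustering follows the correlation structure", {
  set.seed(2)
  base <- rnorm(2000)
  m0 <- base
  mp1 <- 0.8 * base + sqrt(1 - 0.64) * rnorm(2000)
  mm1 <- 0.1 * base + sqrt(1 - 0.01) * rnorm(2000)
  maps <- rbind(`lag_-1` = mm1, lag_0 = m0, lag_1 = mp1)
  lk <- cluster_lag_maps(maps)
  # brute-force distance oracle: the closest pair must merge first
  d <- 1 - cor(t(maps))
  closest <- sort(rownames(maps)[arrayInd(which.min(d + diag(3)), c(3, 3))])
  expect_setequal(first_merge(lk), closest)
  expect_setequal(first_merge(lk), c("lag_0", "lag_1"))
  # identical maps merge at height zero
  same <- cluster_lag_maps(rbind(a = base, b = base, c = base))
  expect_true(all(abs(same$merge_sequence$height) < 1e-12))
  # permutation invariance of the two-cluster partition
  perm <- cluster_lag_maps(maps[c(3, 1, 2), ])
  expect_equal(perm$labels2[["lag_-1"]] == perm$labels2[["lag_0"]],
               lk$labels2[["lag_-1"]] == lk$labels2[["lag_0"]])
  expect_error(cluster_lag_maps(rbind(a = rep(1, 10), b = rnorm(10),
                                      c = rnorm(10))), "constant")
})
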