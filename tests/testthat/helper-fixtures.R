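# Shared fixtures: everything is generated in code at test time.

# tiny desk-scale setup used across module tests
tiny_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(n_subjects = 4L, n_scans = 120L,
                                 grid_shape = c(12L, 12L, 6L), seed = seed),
                            list(...))
  do.call(sim_config, args)
}

tiny_truth <- function(cfg = tiny_cfg(), ...) default_ground_truth(cfg, ...)

# a marker set with all markers well inside the stimulus
fixed_markers <- function(times, duration = 100, id = "P01", group = "musician") {
  marker_set(rep(id, length(times)), rep(group, length(times)), times, duration)
}

# brute-force Gaussian kernel-sum oracle for the KDE regressor
kde_oracle <- function(marker_times, tgrid, bw) {
  out <- numeric(length(tgrid))
  for (i in seq_along(tgrid)) {
    acc <- 0
    for (m in marker_times) acc <- acc + dnorm(tgrid[i], mean = m, sd = bw)
    out[i] <- acc
  }
  out
}

# exhaustive-enumeration oracles for the rank tests ------------------------

# signed-rank: all 2^n sign patterns of the given absolute values
signed_rank_oracle <- function(values, mu0 = 0) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_null <- as.vector(signs %*% r)
  list(statistic = W_obs,
       p_greater = mean(W_null >= W_obs),
       p_less = mean(W_null <= W_obs),
       p_two = min(1, 2 * min(mean(W_null >= W_obs), mean(W_null <= W_obs))))
}

# rank-sum: all choose(n1+n2, n1) assignments of the pooled ranks
rank_sum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(n1 + n2, n1)
  U_null <- apply(sets, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  list(statistic = U_obs,
       p_greater = mean(U_null >= U_obs),
       p_less = mean(U_null <= U_obs),
       p_two = min(1, 2 * min(mean(U_null >= U_obs), mean(U_null <= U_obs))))
}

# closed-form OLS oracle via the normal equations
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
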