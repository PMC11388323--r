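test_that("noise-free markers reproduce the boundary times exactly", {
  cfg <- tiny_cfg(marker_jitter_sd = 0, false_alarm_rate = 0)
  truth <- ground_truth(c(30, 60, 90), c(1, 1, 1), grid_shape = cfg$grid_shape)
  mk <- simulate_markers(truth, cfg)
  for (p in unique(mk$participant_id))
    expect_equal(mk$time[mk$participant_id == p], c(30, 60, 90))
  # zero salience is rejected by construction; near-zero yields an empty set
  truth0 <- ground_truth(c(30, 60, 90), rep(1e-12, 3), grid_shape = cfg$grid_shape)
  expect_equal(nrow(simulate_markers(truth0, cfg)), 0L)
})

test_that("marker participation counts follow the salience binomial model", {
  cfg <- sim_config(n_subjects = 18L, n_participants = 36L, n_scans = 80L,
                    tr = 2, grid_shape = c(12L, 12L, 6L),
                    false_alarm_rate = 0, marker_jitter_sd = 0.2, seed = 5L)
  truth <- ground_truth(c(40, 80, 120), c(1, 0.5, 1),
                        grid_shape = cfg$grid_shape)
  mk <- simulate_markers(truth, cfg)
  counts <- vapply(c(40, 80, 120), function(b)
    sum(abs(mk$time - b) < 5), 0L)
  # 99% binomial intervals around (36, 18, 36)
  expect_equal(counts[1], 36L)
  expect_equal(counts[3], 36L)
  expect_gte(counts[2], qbinom(0.005, 36, 0.5))
  expect_lte(counts[2], qbinom(0.995, 36, 0.5))
  # distributional check across seeds for a non-degenerate salience
  reps <- vapply(1:60, function(s) {
    m <- simulate_markers(truth, sim_config(n_subjects = 18L,
                                            n_participants = 36L,
                                            n_scans = 80L, tr = 2,
                                            grid_shape = c(12L, 12L, 6L),
                                            false_alarm_rate = 0,
                                            marker_jitter_sd = 0.2, seed = s))
    sum(abs(m$time - 80) < 5)
  }, 0L)
  gof <- suppressWarnings(chisq.test(
    table(factor(reps <= 18, levels = c(FALSE, TRUE))),
    p = c(1 - pbinom(18, 36, 0.5), pbinom(18, 36, 0.5))))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulation is bit-identical given the seed and validates inputs", {
  cfg <- tiny_cfg(seed = 11L)
  truth <- tiny_truth(cfg)
  expect_identical(simulate_markers(truth, cfg), simulate_markers(truth, cfg))
  expect_identical(simulate_rms(truth, cfg), simulate_rms(truth, cfg))
  v1 <- simulate_volumes(truth, cfg)
  v2 <- simulate_volumes(truth, cfg)
  expect_identical(v1$volumes[[1]]$data, v2$volumes[[1]]$data)
  expect_identical(v1$timecourses, v2$timecourses)
  expect_error(sim_config(marker_jitter_sd = -1), class = "eventseg_config_error")
  expect_error(sim_config(false_alarm_rate = -0.1), class = "eventseg_config_error")
  expect_error(sim_config(rms_boundary_corr = 1.5), class = "eventseg_config_error")
  short <- sim_config(n_scans = 20L, grid_shape = c(12L, 12L, 6L))
  expect_error(simulate_markers(tiny_truth(), short),
               class = "eventseg_config_error")
})

test_that("simulated RMS hits the target correlation and stays positive", {
  for (r in c(0, 0.5, 0.9)) {
    cfg <- tiny_cfg(rms_boundary_corr = r, seed = 3L)
    truth <- tiny_truth(cfg)
    rms <- simulate_rms(truth, cfg)
    s <- eventseg:::true_salience_scans(truth, cfg)
    expect_lt(abs(cor(rms, s) - r), 0.05)
    expect_true(all(rms > 0))
  }
})

test_that("noise-free single-network volumes are proportional to the regressor", {
  cfg <- tiny_cfg(rms_amplitude = 0, seed = 2L)
  truth <- ground_truth(c(30, 60, 90), c(1, 0.7, 1),
                        grid_shape = cfg$grid_shape,
                        lag_weights = rbind(early = c(0, 1, 0),
                                            transition = c(0, 0, 0)),
                        coupling_coeff = 0, snr = Inf,
                        group_gain = c(musician = 1, nonmusician = 1))
  sim <- simulate_volumes(truth, cfg, identity = TRUE)
  reg <- eventseg:::true_salience_scans(truth, cfg)
  m_lin <- which(sim$mask)
  w <- truth$network_maps$early[m_lin]
  vox <- which(w > 0.5 * max(w))
  for (v in vox[1:5]) {
    series <- sim$volumes[[1]]$data[, v]
    expect_equal(series / w[v], reg, tolerance = 1e-10)
  }
})

test_that("planted coupling is recovered by a lagged OLS oracle", {
  cfg <- sim_config(n_subjects = 1L, n_scans = 200L,
                    grid_shape = c(12L, 12L, 6L), seed = 9L)
  truth <- ground_truth(c(40, 80, 120), c(1, 1, 1),
                        grid_shape = cfg$grid_shape,
                        lag_weights = matrix(0, 2, 3), coupling_coeff = 0.4)
  tcs <- simulate_network_timecourses(truth, cfg)
  slopes <- vapply(tcs$timecourses, function(tc) {
    y <- tc[-1, "transition"]; x1 <- tc[-nrow(tc), "early"]
    unname(ols_oracle(cbind(1, x1), y)[2])
  }, 0)
  expect_true(all(abs(slopes - 0.4) < 0.1))
  # zero coupling: lagged cross-correlation of the innovations is null
  truth0 <- ground_truth(c(40, 80, 120), c(1, 1, 1),
                         grid_shape = cfg$grid_shape,
                         lag_weights = matrix(0, 2, 3), coupling_coeff = 0)
  tc0 <- simulate_network_timecourses(truth0, cfg)$timecourses[[1]]
  cc <- cor(tc0[-1, "transition"], tc0[-nrow(tc0), "early"])
  expect_lt(abs(cc), 2.6 / sqrt(cfg$n_scans))
})

test_that("in-network voxels track their generating time course above noise", {
  cfg <- tiny_cfg(n_scans = 150L, seed = 4L)
  truth <- tiny_truth(cfg)  # snr 1
  sim <- simulate_volumes(truth, cfg)
  m_lin <- which(sim$mask)
  tc <- sim$timecourses[[1]]
  dat <- sim$volumes[[1]]$data
  for (net in c("early", "transition")) {
    w <- truth$network_maps[[net]][m_lin]
    inside <- which(w > 0.5 * max(w))
    outside <- which(w == 0 &
                       truth$network_maps$early[m_lin] == 0 &
                       truth$network_maps$transition[m_lin] == 0)
    set.seed(1)
    r_in <- abs(cor(dat[, inside], tc[, net]))
    r_out <- abs(cor(dat[, sample(outside, 100)], tc[, net]))
    expect_gte(mean(outer(r_in[, 1], r_out[, 1], ">")), 0.99)
  }
})

test_that("network maps are non-negative, disjoint above half-maximum, and sized to the grid", {
  maps <- make_network_maps(c(20L, 20L, 10L))
  expect_true(all(maps$early >= 0) && all(maps$transition >= 0))
  overlap <- maps$early > 0.5 * max(maps$early) &
    maps$transition > 0.5 * max(maps$transition)
  expect_false(any(overlap))
  expect_error(make_network_maps(c(4L, 4L, 3L), sigma = 2.5), "too small")
})
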