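# Synthetic-data generator: boundary marker point processes, an RMS-like
# amplitude confound, and 4-D volumes containing two planted spatial networks
# whose time courses load on the boundary regressor at specific lags, with
# unidirectional causal coupling between them. Gives every downstream stage a
# known ground truth.

#' Planted spatial network maps
#'
#' Two 3-D Gaussian blobs on the voxel grid, thresholded at a fraction of
#' their peak so each map has compact support, placed apart so they are
#' disjoint above half-maximum.
#'
#' @param grid_shape Integer vector of voxel counts per axis (3-D).
#' @param centers Optional 2x3 matrix of blob centres (voxel units, 1-based);
#'   defaults to 1/4 and 3/4 along the first axis.
#' @param sigma Blob standard deviation in voxels.
#' @param floor_frac Weights below `floor_frac * peak` are zeroed.
#' @return A list of two numeric arrays (`early`, `transition`) of dimension
#'   `grid_shape`.
#' @export
make_network_maps <- function(grid_shape = c(20L, 20L, 10L), centers = NULL,
                              sigma = NULL, floor_frac = 0.01) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  sigma <- sigma %||% min(2.5, grid_shape[1] / 8)
  if (is.null(centers)) {
    centers <- rbind(c(grid_shape[1] * 0.28, grid_shape[2] / 2, grid_shape[3] / 2),
                     c(grid_shape[1] * 0.72, grid_shape[2] / 2, grid_shape[3] / 2))
  }
  stopifnot(is.matrix(centers), nrow(centers) == 2L, ncol(centers) == 3L)
  co <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                    z = seq_len(grid_shape[3]))
  blob <- function(ctr) {
    d2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
    w <- exp(-d2 / (2 * sigma^2))
    w[w < floor_frac * max(w)] <- 0
    array(w, dim = grid_shape)
  }
  maps <- list(early = blob(centers[1, ]), transition = blob(centers[2, ]))
  if (any(maps$early > 0.5 * max(maps$early) & maps$transition > 0.5 * max(maps$transition)))
    stop("grid too small to place two networks disjoint above half-maximum")
  maps
}

#' Ground truth for the synthetic study
#'
#' Bundles everything the generator plants: boundary times and saliences, two
#' spatial network maps, per-network lag weights (the "early" network loads at
#' lag -1, the "transition" network at lags 0 and +1), the unidirectional
#' VAR coupling coefficient from the early to the transition network, a
#' per-group gain on the lag weights, AR(1) noise memory, and the
#' signal-to-noise ratio (SD of the strongest voxel's network signal over the
#' noise SD).
#'
#' @param boundary_times Strictly increasing boundary times in seconds.
#' @param boundary_salience Per-boundary marking probability in (0, 1].
#' @param grid_shape Voxel grid dimensions.
#' @param network_maps Optional list as from [make_network_maps()].
#' @param lag_weights 2x3 matrix (rows early/transition, columns lags
#'   -1, 0, +1) of loading weights.
#' @param coupling_coeff VAR cross-coefficient early -> transition (the
#'   transition network never feeds back).
#' @param group_gain Named per-group multiplicative gain on the lag weights.
#' @param noise_ar1 AR(1) coefficient of the voxel noise, in [0, 1).
#' @param snr Signal-to-noise ratio (see above).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(boundary_times, boundary_salience,
                         grid_shape = c(20L, 20L, 10L), network_maps = NULL,
                         lag_weights = rbind(early = c(1, 0, 0),
                                             transition = c(0, 1, 0.8)),
                         coupling_coeff = 0.4,
                         group_gain = c(musician = 1.5, nonmusician = 1),
                         noise_ar1 = 0.3, snr = 1) {
  stopifnot(length(boundary_times) == length(boundary_salience))
  if (length(boundary_times) && any(diff(boundary_times) <= 0))
    stop("boundary times must be strictly increasing")
  if (any(boundary_salience <= 0 | boundary_salience > 1))
    stop("boundary salience must lie in (0, 1]")
  if (!is.matrix(lag_weights) || any(dim(lag_weights) != c(2L, 3L)))
    stop("lag_weights must be a 2 x 3 matrix (networks x lags -1,0,+1)")
  if (coupling_coeff < 0) stop("coupling is unidirectional early -> transition; use a nonnegative coefficient")
  if (noise_ar1 < 0 || noise_ar1 >= 1) stop("noise_ar1 must lie in [0, 1)")
  if (snr <= 0) stop("snr must be positive")
  maps <- network_maps %||% make_network_maps(grid_shape)
  if (any(vapply(maps, min, 0) < 0)) stop("network maps must be non-negative")
  colnames(lag_weights) <- c("-1", "0", "1")
  rownames(lag_weights) <- c("early", "transition")
  structure(list(boundary_times = as.numeric(boundary_times),
                 boundary_salience = as.numeric(boundary_salience),
                 grid_shape = as.integer(grid_shape),
                 network_maps = maps, lag_weights = lag_weights,
                 coupling_coeff = coupling_coeff, group_gain = group_gain,
                 noise_ar1 = noise_ar1, snr = snr),
            class = "ground_truth")
}

#' Default ground truth at desk scale
#'
#' Boundaries every ~28 s (a plausible phrase rate for the three-genre
#' naturalistic stimuli the design emulates) with cycling salience, on a
#' 300 s stimulus by default.
#'
#' @param cfg A [sim_config()]; its `n_scans * tr` sets the duration.
#' @param ... Passed on to [ground_truth()].
#' @return A `ground_truth`.
#' @export
default_ground_truth <- function(cfg = sim_config(), ...) {
  duration <- cfg$n_scans * cfg$tr
  times <- seq(20, duration - 24, by = 28)
  sal <- rep(c(1, 0.55, 0.85, 0.4, 0.7), length.out = length(times))
  ground_truth(times, sal, grid_shape = cfg$grid_shape, ...)
}

#' Simulation configuration
#'
#' @param n_subjects Scanned subjects per group (two groups).
#' @param n_participants Behavioural participants providing boundary markers.
#' @param n_scans Number of scans.
#' @param tr Repetition time in seconds.
#' @param grid_shape Voxel grid dimensions.
#' @param marker_jitter_sd SD of Gaussian marker timing jitter, seconds.
#' @param false_alarm_rate Spurious markers per participant per minute.
#' @param rms_boundary_corr Target Pearson correlation between the simulated
#'   RMS confound and the true boundary-salience regressor, in [-1, 1].
#' @param rms_amplitude Amplitude of the RMS contribution to voxel signals,
#'   as a fraction of the noise SD.
#' @param seed Integer master seed; together with the ground truth it fully
#'   determines all generated data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L, n_participants = 2L * n_subjects,
                       n_scans = 150L, tr = 2, grid_shape = c(20L, 20L, 10L),
                       marker_jitter_sd = 0.5, false_alarm_rate = 0.5,
                       rms_boundary_corr = 0.05, rms_amplitude = 0.5,
                       seed = 1L) {
  if (marker_jitter_sd < 0) stop_config("marker_jitter_sd must be >= 0")
  if (false_alarm_rate < 0) stop_config("false_alarm_rate must be >= 0")
  if (abs(rms_boundary_corr) > 1) stop_config("rms_boundary_corr must lie in [-1, 1]")
  stopifnot(is_count(n_subjects), is_count(n_scans), tr > 0,
            length(grid_shape) == 3L)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_participants = as.integer(n_participants),
                 n_scans = as.integer(n_scans), tr = tr,
                 grid_shape = as.integer(grid_shape),
                 marker_jitter_sd = marker_jitter_sd,
                 false_alarm_rate = false_alarm_rate,
                 rms_boundary_corr = rms_boundary_corr,
                 rms_amplitude = rms_amplitude,
                 seed = as.integer(seed)),
            class = "sim_config")
}

check_truth_cfg <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  dur <- cfg$n_scans * cfg$tr
  if (length(truth$boundary_times) &&
      dur < max(truth$boundary_times) + 20)
    stop_config("n_scans * tr must cover the last boundary plus 20 s")
  dur
}

# true salience series on the scan grid: Gaussian-kernel smoothed boundary
# train weighted by salience (the noise-free analogue of the KDE regressor)
true_salience_scans <- function(truth, cfg, bandwidth = 2) {
  scan_t <- (seq_len(cfg$n_scans) - 1) * cfg$tr
  if (!length(truth$boundary_times)) return(numeric(cfg$n_scans))
  colSums(truth$boundary_salience *
            dnorm(outer(truth$boundary_times, scan_t, "-") / bandwidth)) / bandwidth
}

#' Simulate per-participant boundary markers
#'
#' Each participant marks boundary k with probability equal to its salience,
#' at the true time plus Gaussian jitter, and adds uniformly-timed false
#' alarms at `false_alarm_rate` per minute. Markers are clamped to the
#' stimulus interval.
#'
#' @param truth A [ground_truth()].
#' @param cfg A [sim_config()].
#' @return A [marker_set()].
#' @export
simulate_markers <- function(truth, cfg) {
  duration <- check_truth_cfg(truth, cfg)
  half <- ceiling(cfg$n_participants / 2)
  groups <- rep(c("musician", "nonmusician"), c(half, cfg$n_participants - half))
  withr::with_seed(derive_seed(cfg$seed, 101L), {
    out <- lapply(seq_len(cfg$n_participants), function(p) {
      hit <- runif(length(truth$boundary_times)) < truth$boundary_salience
      t_hits <- truth$boundary_times[hit] +
        rnorm(sum(hit), sd = cfg$marker_jitter_sd)
      n_fa <- rpois(1L, cfg$false_alarm_rate * duration / 60)
      tt <- sort(pmin(pmax(c(t_hits, runif(n_fa, 0, duration)), 0), duration))
      if (!length(tt)) return(NULL)
      data.frame(participant_id = sprintf("P%02d", p), group = groups[p],
                 time = tt, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(participant_id = character(),
                                      group = character(), time = numeric())
  marker_set(out$participant_id, out$group, out$time, duration)
}

#' Simulate the RMS amplitude confound
#'
#' A strictly positive, temporally smooth per-scan series whose in-sample
#' Pearson correlation with the true boundary-salience regressor equals
#' `cfg$rms_boundary_corr` exactly, built by mixing the standardized salience
#' series with an orthogonalized smooth noise series.
#'
#' @param truth A [ground_truth()].
#' @param cfg A [sim_config()].
#' @return Numeric vector of `n_scans` strictly positive values.
#' @export
simulate_rms <- function(truth, cfg) {
  check_truth_cfg(truth, cfg)
  r <- cfg$rms_boundary_corr
  n <- cfg$n_scans
  if (n < 10L) stop("cannot construct a correlated smooth confound with fewer than 10 scans")
  s <- true_salience_scans(truth, cfg)
  if (sd(s) == 0) stop("degenerate salience regressor: no boundaries")
  withr::with_seed(derive_seed(cfg$seed, 202L), {
    raw <- rnorm(n + 20L)
  })
  ksm <- dnorm(seq(-3, 3, length.out = 7L)); ksm <- ksm / sum(ksm)
  sm <- convolve(raw, rev(ksm), type = "open")
  noise <- sm[11:(10L + n)]
  s_std <- (s - mean(s)) / sd(s)
  e <- noise - mean(noise)
  e <- e - s_std * sum(e * s_std) / sum(s_std^2)
  if (sd(e) == 0) stop("cannot orthogonalize confound noise for this n_scans")
  e_std <- e / sd(e)
  x <- r * s_std + sqrt(1 - r^2) * e_std
  x - min(x) + 0.1
}

#' Simulate per-subject network time courses
#'
#' For each scanned subject, the early and transition network time courses
#' are built from the HRF-convolved, lag-weighted boundary regressor scaled
#' by the subject's group gain, plus a unidirectional VAR coupling term (past
#' of the early network driving the present of the transition network) and
#' Gaussian innovation noise with SD `sd(drive) / snr`.
#'
#' @param truth A [ground_truth()].
#' @param cfg A [sim_config()].
#' @param regressor Scan-grid salience values (defaults to the true
#'   noise-free salience series).
#' @param hrf Optional HRF kernel; `identity = TRUE` skips convolution.
#' @param identity Use an identity HRF.
#' @return A list with `timecourses` (list of `n_scans x 2` matrices, one per
#'   subject), `groups`, `subject_ids`, and the per-network drives.
#' @export
simulate_network_timecourses <- function(truth, cfg, regressor = NULL,
                                         hrf = NULL, identity = FALSE) {
  check_truth_cfg(truth, cfg)
  reg <- regressor %||% true_salience_scans(truth, cfg)
  if (inherits(reg, "boundary_regressor")) reg <- reg$scan_values
  stopifnot(length(reg) == cfg$n_scans)
  lags <- c(-1L, 0L, 1L)
  lagged <- vapply(lags, function(l)
    hrf_convolve(lag_regressor(reg, l), cfg$tr, hrf, identity),
    numeric(cfg$n_scans))
  drives <- lagged %*% t(truth$lag_weights)  # n_scans x 2
  n_total <- 2L * cfg$n_subjects
  groups <- rep(names(truth$group_gain)[1:2], each = cfg$n_subjects)
  sd_drive <- max(apply(drives, 2, sd))
  innov_sd <- if (sd_drive > 0) sd_drive / truth$snr else 1
  tcs <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    gain <- truth$group_gain[[groups[s]]]
    withr::with_seed(derive_seed(cfg$seed, 300L + s), {
      e <- matrix(rnorm(cfg$n_scans * 2L, sd = innov_sd), ncol = 2L)
    })
    tc1 <- gain * drives[, 1] + e[, 1]
    tc2 <- gain * drives[, 2] + truth$coupling_coeff * lag_regressor(tc1, 1L) + e[, 2]
    tcs[[s]] <- cbind(early = tc1, transition = tc2)
  }
  list(timecourses = tcs, groups = groups,
       subject_ids = sprintf("S%02d", seq_len(n_total)),
       drives = drives, innovation_sd = innov_sd)
}

#' Simulate subject 4-D volumes with planted networks
#'
#' Voxel data are the network maps times their subject time courses, plus a
#' global RMS confound contribution, plus AR(1) Gaussian noise scaled so that
#' the SD of the strongest in-network voxel's signal over the noise SD equals
#' `truth$snr`.
#'
#' @inheritParams simulate_network_timecourses
#' @param rms Optional per-scan RMS series to embed (defaults to
#'   [simulate_rms()]).
#' @param mask Optional logical array; defaults to the full grid.
#' @return A list with `volumes` (list of [volume_series()]), `timecourses`,
#'   `groups`, `rms`, and `mask`.
#' @export
simulate_volumes <- function(truth, cfg, regressor = NULL, rms = NULL,
                             hrf = NULL, identity = FALSE, mask = NULL) {
  check_truth_cfg(truth, cfg)
  mask <- mask %||% array(TRUE, dim = cfg$grid_shape)
  if (!all(dim(mask) == cfg$grid_shape))
    stop(sprintf("mask shape (%s) does not match grid shape (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(cfg$grid_shape, collapse = "x")))
  m_lin <- which(mask)
  maps_mat <- cbind(early = truth$network_maps$early[m_lin],
                    transition = truth$network_maps$transition[m_lin])
  sim_tc <- simulate_network_timecourses(truth, cfg, regressor, hrf, identity)
  rms <- rms %||% simulate_rms(truth, cfg)
  rms_c <- (rms - mean(rms)) / max(sd(rms), .Machine$double.eps)
  # noise scale: strongest in-network voxel's signal SD (at group gain 1)
  sig_sd <- max(apply(maps_mat, 2, max) * apply(sim_tc$drives, 2, sd))
  noise_sd <- if (sig_sd > 0) sig_sd / truth$snr else 1
  vols <- vector("list", length(sim_tc$timecourses))
  for (s in seq_along(vols)) {
    signal <- sim_tc$timecourses[[s]] %*% t(maps_mat)
    withr::with_seed(derive_seed(cfg$seed, 7000L + s), {
      innov <- matrix(rnorm(cfg$n_scans * length(m_lin)), nrow = cfg$n_scans)
    })
    w_sd <- noise_sd * sqrt(1 - truth$noise_ar1^2)
    noise <- if (truth$noise_ar1 > 0)
      matrix(as.numeric(stats::filter(innov * w_sd, truth$noise_ar1,
                                      method = "recursive")),
             nrow = cfg$n_scans)
    else innov * w_sd
    data <- signal + cfg$rms_amplitude * noise_sd *
      outer(rms_c, rep(1, length(m_lin))) + noise
    vols[[s]] <- volume_series(data, mask, cfg$tr,
                               subject_id = sim_tc$subject_ids[s],
                               group = sim_tc$groups[s])
  }
  list(volumes = vols, timecourses = sim_tc$timecourses,
       groups = sim_tc$groups, subject_ids = sim_tc$subject_ids,
       rms = rms, mask = mask, noise_sd = noise_sd, drives = sim_tc$drives)
}

#' Simulate a coupled AR(1) pair for Granger-causality validation
#'
#' `x` is an autonomous AR(1) process; `y` is AR(1) driven by the past of `x`
#' with the given coupling coefficient. This isolates the causal mechanism:
#' with `coupling = 0` the two series are independent, so the null arm of a
#' calibration experiment is exact.
#'
#' @param n Series length.
#' @param coupling Cross-coefficient from `x[t-1]` to `y[t]`.
#' @param ar AR(1) coefficients for x and y.
#' @param seed Integer seed.
#' @param burn Burn-in samples discarded.
#' @return A two-column matrix `cbind(x, y)`.
#' @export
simulate_var_pair <- function(n, coupling = 0.4, ar = c(0.3, 0.3), seed = 1L,
                              burn = 50L) {
  stopifnot(is_count(n), length(ar) == 2L)
  withr::with_seed(seed, {
    e <- matrix(rnorm((n + burn) * 2L), ncol = 2L)
  })
  x <- as.numeric(stats::filter(e[, 1], ar[1], method = "recursive"))
  stopifnot(!anyNA(x))
  y <- numeric(n + burn)
  for (t in 2:(n + burn)) y[t] <- ar[2] * y[t - 1] + coupling * x[t - 1] + e[t, 2]
  cbind(x = x[(burn + 1):(burn + n)], y = y[(burn + 1):(burn + n)])
}
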