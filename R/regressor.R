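# Boundary-salience regressor: kernel density estimation over pooled listener
# markers, resampling to the scan grid, lagging, and hemodynamic convolution.

#' Construct a marker set
#'
#' A marker set holds the real-time boundary markers laid down by listeners:
#' one row per marker with the participant identifier, the participant's group
#' and the marker time in seconds from stimulus onset.
#'
#' @param participant_id Character or factor, one entry per marker.
#' @param group Group label per marker (e.g. `"musician"`, `"nonmusician"`).
#' @param time Marker times in seconds, within `[0, duration]`.
#' @param duration Stimulus duration in seconds.
#' @return An object of class `marker_set` (a data frame with a `duration`
#'   attribute).
#' @export
marker_set <- function(participant_id, group, time, duration) {
  stopifnot(length(participant_id) == length(time), length(group) == length(time))
  if (length(time) && (any(time < 0) || any(time > duration)))
    stop("marker times must lie within [0, duration]")
  x <- data.frame(participant_id = as.character(participant_id),
                  group = as.character(group),
                  time = as.numeric(time),
                  stringsAsFactors = FALSE)
  x <- x[order(x$participant_id, x$time), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, duration = as.numeric(duration), class = c("marker_set", "data.frame"))
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers, %d participants, duration %.1f s\n",
              nrow(x), length(unique(x$participant_id)), attr(x, "duration")))
  invisible(x)
}

#' Estimate the continuous boundary-salience regressor by KDE
#'
#' Pools boundary markers across participants and evaluates an unnormalized
#' Gaussian kernel density on a fine regular grid over the stimulus. The
#' density at time t is the sum over all markers m of
#' `dnorm(t, mean = m, sd = bandwidth)`, so it is on the scale of
#' "marking participants per second" and integrates to the total marker count.
#' Its height at a boundary measures the degree of cross-listener consensus
#' that a boundary occurred there: the boundary salience.
#'
#' @param markers A [marker_set()].
#' @param bandwidth Gaussian kernel standard deviation in seconds.
#' @param grid_step Fine-grid spacing in seconds.
#' @param normalize If `TRUE`, scale the density to integrate to 1 instead of
#'   to the marker count.
#' @param groups Optional character vector restricting the pooled markers to
#'   the given group labels (the default pools across participant groups).
#' @return An object of class `boundary_regressor` with fields `time`,
#'   `density`, `bandwidth`, `grid_step`, `duration`, and (after
#'   [resample_to_scans()]) `scan_values` and `tr`.
#' @export
estimate_salience <- function(markers, bandwidth = 2, grid_step = 0.1,
                              normalize = FALSE, groups = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  if (!is.numeric(grid_step) || grid_step <= 0) stop("grid_step must be > 0")
  duration <- attr(markers, "duration")
  if (!is.null(groups)) markers <- markers[markers$group %in% groups, , drop = FALSE]
  tgrid <- seq(0, duration, by = grid_step)
  if (tgrid[length(tgrid)] < duration) tgrid <- c(tgrid, duration)
  m <- markers$time
  if (length(m) == 0L) {
    warning("empty marker set: returning an identically zero regressor")
    dens <- numeric(length(tgrid))
  } else {
    # vectorised kernel sum; chunk over markers to bound memory
    dens <- numeric(length(tgrid))
    chunk <- 512L
    for (i in seq(1L, length(m), by = chunk)) {
      mm <- m[i:min(i + chunk - 1L, length(m))]
      dens <- dens + colSums(dnorm(outer(mm, tgrid, "-") / bandwidth)) / bandwidth
    }
    if (normalize) dens <- dens / length(m)
  }
  structure(list(time = tgrid, density = dens, bandwidth = bandwidth,
                 grid_step = grid_step, duration = duration,
                 normalized = normalize, scan_values = NULL, tr = NULL),
            class = "boundary_regressor")
}

#' @export
print.boundary_regressor <- function(x, ...) {
  cat(sprintf("<boundary_regressor> duration %.1f s, bandwidth %.2f s, grid step %.3f s\n",
              x$duration, x$bandwidth, x$grid_step))
  if (!is.null(x$scan_values))
    cat(sprintf("  resampled: %d scans at TR %.2f s\n", length(x$scan_values), x$tr))
  invisible(x)
}

#' Resample a boundary regressor to the scan grid
#'
#' Linearly interpolates the fine-grid density at scan frame onsets
#' `t = i * tr` for 0-based scan index `i`.
#'
#' @param reg A `boundary_regressor`.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans.
#' @return The regressor with `scan_values` and `tr` filled in.
#' @export
resample_to_scans <- function(reg, tr, n_scans) {
  stopifnot(inherits(reg, "boundary_regressor"), is_count(n_scans), tr > 0)
  scan_t <- (seq_len(n_scans) - 1) * tr
  if (max(scan_t) > max(reg$time) + 1e-9)
    stop(sprintf("scan grid extends to %.2f s but fine grid ends at %.2f s",
                 max(scan_t), max(reg$time)))
  reg$scan_values <- approx(reg$time, reg$density, xout = scan_t)$y
  reg$tr <- tr
  reg
}

#' Time-shift a scan-grid series by an integer number of scans
#'
#' `out[i] = x[i - lag]`; samples shifted in from beyond either edge are
#' zero-filled. Positive lag shifts the series later in time, modelling a
#' response that follows the boundary; lag -1 models pre-boundary response.
#'
#' @param x Numeric scan-grid series, or a resampled `boundary_regressor`.
#' @param lag Integer lag in scans, `abs(lag) < length(x)`.
#' @return Numeric series of the same length.
#' @export
lag_regressor <- function(x, lag) {
  if (inherits(x, "boundary_regressor")) {
    if (is.null(x$scan_values)) stop("regressor has not been resampled to the scan grid")
    x <- x$scan_values
  }
  stopifnot(is.numeric(x), length(lag) == 1L, lag == round(lag))
  n <- length(x)
  if (abs(lag) >= n) stop("abs(lag) must be smaller than the series length")
  lag <- as.integer(lag)
  if (lag == 0L) return(x)
  if (lag > 0L) c(numeric(lag), x[seq_len(n - lag)])
  else c(x[(1L - lag):n], numeric(-lag))
}

#' Canonical double-gamma haemodynamic response function sampled at TR
#'
#' Difference of two gamma densities (response peak near 6 s, undershoot near
#' 16 s), truncated at `duration` and normalized to unit sum so convolution
#' preserves the amplitude of sustained input.
#'
#' @param tr Sampling interval (repetition time), seconds.
#' @param duration Kernel support in seconds.
#' @param peak,undershoot Gamma shape parameters (rate 1) for the positive
#'   response and the undershoot.
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @return Numeric kernel sampled at `0, tr, 2*tr, ...`.
#' @export
canonical_hrf <- function(tr, duration = 32, peak = 6, undershoot = 16,
                          undershoot_ratio = 1 / 6) {
  t <- seq(0, duration, by = tr)
  h <- dgamma(t, shape = peak, rate = 1) -
    undershoot_ratio * dgamma(t, shape = undershoot, rate = 1)
  h / sum(h)
}

#' Convolve a scan-grid series with a haemodynamic response function
#'
#' Causal discrete convolution truncated to the input length. With
#' `identity = TRUE` the input is returned unchanged, which is useful for
#' exactness tests of the surrounding machinery.
#'
#' @param x Numeric scan-grid series.
#' @param tr Repetition time in seconds (used for the default kernel).
#' @param hrf Optional kernel; defaults to [canonical_hrf()] at `tr`.
#' @param identity If `TRUE`, skip convolution.
#' @return Numeric series of the same length as `x`.
#' @export
hrf_convolve <- function(x, tr = 2, hrf = NULL, identity = FALSE) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (identity) return(x)
  h <- hrf %||% canonical_hrf(tr)
  y <- convolve(x, rev(h), type = "open")
  y[seq_along(x)]
}

#' Per-scan root-mean-square amplitude of a waveform
#'
#' Value i is the RMS of the samples in the window `[i*tr, (i+1)*tr)` (0-based
#' scan index), the standard amplitude-envelope confound for auditory fMRI.
#'
#' @param waveform Numeric mono waveform samples.
#' @param rate Sampling rate in Hz.
#' @param tr Window length (repetition time) in seconds.
#' @param n_scans Number of windows.
#' @return Numeric vector of `n_scans` RMS values.
#' @export
compute_rms <- function(waveform, rate, tr, n_scans) {
  if (length(waveform) == 0L) stop("empty waveform")
  stopifnot(is.numeric(waveform), rate > 0, tr > 0, is_count(n_scans))
  w <- round(tr * rate)
  if (length(waveform) < n_scans * w)
    stop("waveform shorter than n_scans * tr")
  idx <- matrix(waveform[seq_len(n_scans * w)]^2, nrow = w)
  sqrt(colMeans(idx))
}

#' Association checks between the boundary regressor and the RMS confound
#'
#' Pearson and Spearman correlations with two-sided p-values, used to verify
#' that the boundary regressor does not simply track stimulus loudness.
#'
#' @param reg Numeric scan-grid regressor values.
#' @param rms Numeric scan-grid RMS values.
#' @return A `confound_check` list with `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, and `n`.
#' @export
check_confound <- function(reg, rms) {
  if (inherits(reg, "boundary_regressor")) reg <- reg$scan_values
  stopifnot(is.numeric(reg), is.numeric(rms))
  if (length(reg) != length(rms)) stop("series lengths differ")
  if (length(reg) < 3L) stop("need at least 3 scans")
  if (sd(reg) == 0 || sd(rms) == 0)
    stop("zero-variance input: correlation undefined")
  pe <- cor.test(reg, rms, method = "pearson")
  sp <- suppressWarnings(cor.test(reg, rms, method = "spearman", exact = FALSE))
  structure(list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n = length(reg)),
            class = "confound_check")
}

#' @export
print.confound_check <- function(x, ...) {
  cat(sprintf("<confound_check> n = %d: Pearson r = %.3f (p = %.3g), Spearman rho = %.3f (p = %.3g)\n",
              x$n, x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Build the lagged GLM design matrix from a scan-grid regressor
#'
#' One column per requested lag (default -1, 0, +1 scans: pre-boundary, at
#' boundary, post-boundary), each optionally convolved with the canonical HRF,
#' plus an intercept.
#'
#' @param scan_values Numeric scan-grid regressor, or a resampled
#'   `boundary_regressor`.
#' @param lags Integer lags in scans.
#' @param tr Repetition time in seconds.
#' @param convolve Convolve each lagged copy with the HRF (recommended for
#'   BOLD data; disable for exactness tests).
#' @param hrf Optional HRF kernel passed to [hrf_convolve()].
#' @return Numeric matrix `n_scans x (1 + length(lags))` with an `"(intercept)"`
#'   column and one `lag_<l>` column per lag; lags stored in attribute `lags`.
#' @export
build_lag_design <- function(scan_values, lags = c(-1L, 0L, 1L), tr = 2,
                             convolve = TRUE, hrf = NULL) {
  if (inherits(scan_values, "boundary_regressor")) {
    tr <- scan_values$tr %||% tr
    scan_values <- scan_values$scan_values
  }
  stopifnot(is.numeric(scan_values), length(lags) >= 1L)
  cols <- vapply(lags, function(l) {
    s <- lag_regressor(scan_values, l)
    if (convolve) hrf_convolve(s, tr, hrf) else s
  }, numeric(length(scan_values)))
  X <- cbind(1, cols)
  colnames(X) <- c("(intercept)", paste0("lag_", lags))
  attr(X, "lags") <- as.integer(lags)
  X
}
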