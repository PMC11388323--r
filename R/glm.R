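# Voxelwise lagged GLM: RMS confound removal, per-subject OLS with one
# column per lag of the boundary regressor, Fisher combined-probability
# pooling across subjects, and rank-based lag / group comparisons.

#' Regress the RMS confound out of every voxel time series
#'
#' Replaces each in-mask voxel time series by its residual after ordinary
#' least squares on an intercept and the confound, so the residual data carry
#' no linear trace of stimulus loudness. Residuals have exactly zero sample
#' correlation with the confound up to numerical precision.
#'
#' @param vol A [volume_series()].
#' @param confound Numeric per-scan confound (e.g. RMS amplitude).
#' @return The volume series with residual data.
#' @export
regress_out_confound <- function(vol, confound) {
  stopifnot(inherits(vol, "volume_series"))
  if (length(confound) != nrow(vol$data))
    stop("confound length must equal the number of scans")
  if (sd(confound) == 0) stop("constant confound: nothing to regress out")
  qx <- qr(cbind(1, confound))
  vol$data <- qr.resid(qx, vol$data)
  vol
}

#' Fit the lagged boundary GLM for one subject
#'
#' Joint ordinary least squares of every in-mask voxel on the full lagged
#' design (all lag columns in one model, so shared variance between the
#' heavily overlapping lagged regressors is not double counted). Returns
#' per-voxel betas, t statistics and one-sided p-values per lag. A
#' single-lag mode (`joint = FALSE`) fits one design per lag for comparison.
#'
#' @param vol A [volume_series()].
#' @param design Design matrix from [build_lag_design()] (intercept + lag
#'   columns, attribute `lags`).
#' @param joint Fit all lags jointly (default) or one at a time.
#' @return An object of class `subject_glm` with matrices `betas`, `t_stats`,
#'   `p_pos`, `p_neg` (voxels x lags), residual `dof`, `lags`, and subject
#'   metadata.
#' @export
fit_subject_glm <- function(vol, design, joint = TRUE) {
  stopifnot(inherits(vol, "volume_series"), is.matrix(design))
  lags <- attr(design, "lags")
  if (is.null(lags)) stop("design must carry a 'lags' attribute (see build_lag_design)")
  n <- nrow(vol$data)
  if (nrow(design) != n) stop("design rows must equal the number of scans")
  fit_one <- function(X) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      stop(sprintf("rank-deficient design: collinear column(s) %s",
                   paste(bad, collapse = ", ")))
    }
    B <- qr.coef(qx, vol$data)
    res <- qr.resid(qx, vol$data)
    dof <- n - ncol(X)
    sigma2 <- colSums(res^2) / dof
    covd <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
    se <- sqrt(outer(covd, sigma2))
    list(B = B, t = B / se, dof = dof)
  }
  if (joint) {
    f <- fit_one(design)
    keep <- match(paste0("lag_", lags), colnames(design))
    betas <- t(f$B[keep, , drop = FALSE])
    tval <- t(f$t[keep, , drop = FALSE])
    dof <- f$dof
  } else {
    per <- lapply(seq_along(lags), function(i)
      fit_one(design[, c(1L, i + 1L), drop = FALSE]))
    betas <- vapply(per, function(f) f$B[2L, ], numeric(ncol(vol$data)))
    tval <- vapply(per, function(f) f$t[2L, ], numeric(ncol(vol$data)))
    dof <- per[[1L]]$dof
  }
  colnames(betas) <- colnames(tval) <- paste0("lag_", lags)
  p_pos <- pt(tval, dof, lower.tail = FALSE)
  structure(list(betas = betas, t_stats = tval, p_pos = p_pos,
                 p_neg = 1 - p_pos, dof = dof, lags = lags,
                 subject_id = vol$subject_id, group = vol$group),
            class = "subject_glm")
}

#' @export
print.subject_glm <- function(x, ...) {
  cat(sprintf("<subject_glm> %s: %d voxels, lags %s, dof %d\n", x$subject_id,
              nrow(x$betas), paste(x$lags, collapse = ","), x$dof))
  invisible(x)
}

#' Pool one-sided p-values across subjects with Fisher's method
#'
#' Per voxel, the statistic is `-2 * sum(log(p_i))` over the k subjects and
#' the combined p-value comes from the chi-square survival function with 2k
#' degrees of freedom. Activation and deactivation maps are pooled from the
#' corresponding one-sided p-values separately.
#'
#' @param p_values Numeric matrix `subjects x voxels` of one-sided p-values
#'   in (0, 1].
#' @param direction Label recorded on the result.
#' @return A `group_map` list with `stat`, `p`, `df`, `method`, `direction`.
#' @export
fisher_combine <- function(p_values, direction = "activation") {
  p_values <- as.matrix(p_values)
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-values of 0 clipped to the smallest positive representable value")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  k <- nrow(p_values)
  stat <- -2 * colSums(log(p_values))
  group_map(stat = stat, p = pchisq(stat, df = 2 * k, lower.tail = FALSE),
            method = "fisher", direction = direction, df = 2 * k)
}

group_map <- function(stat, p, method, direction = "two-sided", ...) {
  structure(list(stat = stat, p = p, method = method, direction = direction,
                 ...), class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat(sprintf("<group_map> %s (%s): %d voxels, min p = %.3g\n",
              x$method, x$direction, length(x$p), suppressWarnings(min(x$p))))
  invisible(x)
}

#' Compare subject-level lag maps between lag pairs
#'
#' Voxelwise two-tailed Wilcoxon rank-sum comparison of the subject-level
#' statistics between each pair of lags (the convention printed in the
#' source analyses); since lags are measured within subject, a paired
#' signed-rank variant is available via `method = "signed_rank"`.
#'
#' @param subject_maps Named list, one `subjects x voxels` matrix per lag.
#' @param method `"rank_sum"` (default) or `"signed_rank"`.
#' @return A named list of `group_map` objects, one per lag pair, each with
#'   `z` (z-equivalent statistic) and two-tailed `p` per voxel.
#' @export
compare_lags <- function(subject_maps, method = c("rank_sum", "signed_rank")) {
  method <- match.arg(method)
  stopifnot(is.list(subject_maps), length(subject_maps) >= 2L)
  if (is.null(names(subject_maps)))
    names(subject_maps) <- paste0("lag", seq_along(subject_maps))
  pairs <- combn(names(subject_maps), 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    A <- subject_maps[[pr[1]]]; B <- subject_maps[[pr[2]]]
    if (nrow(A) < 2L || nrow(B) < 2L) stop("need at least 2 subjects")
    res <- if (method == "rank_sum") rank_sum_map(A, B) else {
      if (!all(dim(A) == dim(B))) stop("signed-rank comparison needs paired maps")
      signed_rank_map(A - B)
    }
    group_map(stat = res$z, p = res$p, method = paste0("wilcoxon_", method),
              direction = "two-sided", z = res$z)
  })
  names(out) <- vapply(pairs, paste, "", collapse = "_vs_")
  out
}

#' Compare subject-level maps between groups
#'
#' Voxelwise two-sample two-tailed Wilcoxon rank-sum test of subject map
#' values between the two groups (e.g. musicians vs nonmusicians). The
#' z-statistic is signed so that larger values in the first group are
#' positive.
#'
#' @param subject_maps Numeric matrix `subjects x voxels`.
#' @param groups Group label per subject (exactly two distinct labels; the
#'   alphabetically first label is the reference group, so relabelling the
#'   subjects flips the sign of the statistic).
#' @return A `group_map` with per-voxel `z` and two-tailed `p`.
#' @export
compare_groups_glm <- function(subject_maps, groups) {
  subject_maps <- as.matrix(subject_maps)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required")
  A <- subject_maps[groups == lev[1], , drop = FALSE]
  B <- subject_maps[groups == lev[2], , drop = FALSE]
  if (nrow(A) < 2L || nrow(B) < 2L) stop("each group needs at least 2 subjects")
  res <- rank_sum_map(A, B)
  group_map(stat = res$z, p = res$p, method = "wilcoxon_rank_sum",
            direction = "two-sided", z = res$z, groups = lev)
}

#' Distribution-free voxelwise association with the boundary regressor
#'
#' Spearman rank correlation of every in-mask voxel with a scan-grid series,
#' with two-sided p-values (exact permutation null for very short series,
#' t approximation otherwise). Constant voxels are flagged with `NA`.
#'
#' @param vol A [volume_series()].
#' @param reg Numeric scan-grid series.
#' @return List with per-voxel `rho` and `p`.
#' @export
spearman_association <- function(vol, reg) {
  stopifnot(inherits(vol, "volume_series"))
  if (inherits(reg, "boundary_regressor")) reg <- reg$scan_values
  n <- nrow(vol$data)
  if (length(reg) != n) stop("regressor length must equal the number of scans")
  if (n < 3L) stop("need at least 3 scans")
  rr <- rank(reg)
  const <- apply(vol$data, 2L, function(v) min(v) == max(v))
  R <- col_ranks(vol$data)
  rho <- suppressWarnings(as.vector(cor(R, rr)))
  rho[const] <- NA_real_
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho)
  if (n <= 7L && !anyDuplicated(reg)) {
    # exact permutation null: with untied ranks the null distribution of rho
    # is universal across voxels
    perms <- permutations_all(n)
    base <- seq_len(n)
    null_rho <- apply(perms, 1L, function(pp) cor(base, rank(reg)[pp]))
    p[ok] <- vapply(rho[ok], function(r)
      mean(abs(null_rho) >= abs(r) - 1e-12), 0)
  } else {
    tt <- rho[ok] * sqrt((n - 2) / pmax(1 - rho[ok]^2, .Machine$double.eps))
    p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
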