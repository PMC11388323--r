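# Group spatial ICA: per-subject temporal PCA, temporal concatenation, group
# PCA, FastICA fixed-point estimation of spatially independent maps, GICA3
# back-reconstruction of subject-specific maps and time courses, component
# lag-significance profiling and group comparison of subject maps.

#' Two-step dimensionality reduction for group spatial ICA
#'
#' Step one reduces each subject's time dimension to `subject_dim` principal
#' components; the reduced subject data are concatenated along the reduced
#' time axis and step two reduces the concatenation to `group_dim` group
#' components. All projection matrices are retained so subject maps and time
#' courses can be back-reconstructed.
#'
#' @param vols List of [volume_series()] objects with a common mask.
#' @param subject_dim Retained dimensions per subject (<= n_scans).
#' @param group_dim Retained group dimensions (<= subjects * subject_dim).
#' @return An object of class `ica_reduction` holding the group-reduced data
#'   `X` (`group_dim x voxels`), the stacked subject projections, and all
#'   metadata needed by [back_reconstruct_gica3()].
#' @export
reduce_two_step <- function(vols, subject_dim, group_dim) {
  stopifnot(is.list(vols), length(vols) >= 1L, is_count(subject_dim),
            is_count(group_dim))
  N <- length(vols)
  n_scans <- nrow(vols[[1]]$data)
  V <- ncol(vols[[1]]$data)
  if (subject_dim > n_scans)
    stop(sprintf("subject_dim %d exceeds n_scans %d", subject_dim, n_scans))
  if (group_dim > N * subject_dim)
    stop(sprintf("group_dim %d exceeds subjects x subject_dim = %d",
                 group_dim, N * subject_dim))
  subjects <- vector("list", N)
  Y <- matrix(0, N * subject_dim, V)
  for (i in seq_len(N)) {
    v <- vols[[i]]
    stopifnot(nrow(v$data) == n_scans, ncol(v$data) == V)
    ctr <- colMeans(v$data)
    X <- sweep(v$data, 2L, ctr)
    sv <- svd(X, nu = subject_dim, nv = 0)
    achievable <- sum(sv$d > sv$d[1] * 1e-10)
    if (achievable < subject_dim)
      stop(sprintf("subject %d has rank %d < subject_dim %d", i, achievable,
                   subject_dim))
    U <- sv$u
    Y[(i - 1L) * subject_dim + seq_len(subject_dim), ] <- crossprod(U, X)
    subjects[[i]] <- list(U = U, center = ctr, subject_id = v$subject_id,
                          group = v$group)
  }
  svg <- svd(Y, nu = group_dim, nv = 0)
  achievable <- sum(svg$d > svg$d[1] * 1e-10)
  if (achievable < group_dim)
    stop(sprintf("stacked data have rank %d < group_dim %d", achievable,
                 group_dim))
  G <- svg$u
  structure(list(X = crossprod(G, Y), G = G, Y = Y, subjects = subjects,
                 subject_dim = subject_dim, group_dim = group_dim,
                 n_scans = n_scans, n_subjects = N, n_voxels = V,
                 eigenvalues = list(group = svg$d),
                 mask = vols[[1]]$mask, tr = vols[[1]]$tr,
                 groups = vapply(vols, function(v) v$group, ""),
                 subject_ids = vapply(vols, function(v) v$subject_id, "")),
            class = "ica_reduction")
}

#' @export
print.ica_reduction <- function(x, ...) {
  cat(sprintf("<ica_reduction> %d subjects x %d scans -> %d + %d dims, %d voxels\n",
              x$n_subjects, x$n_scans, x$subject_dim, x$group_dim, x$n_voxels))
  invisible(x)
}

# Symmetric FastICA fixed point with log-cosh contrast on whitened rows.
# Near-Gaussian components can trap the plain iteration in a period-2 limit
# cycle; when one is detected the update is damped (sign-aligned average with
# the previous iterate, re-decorrelated), which restores convergence without
# moving the fixed points.
fastica_core <- function(Z, k, seed, alpha = 1, max_iter = 500L, tol = 1e-7,
                         restarts = 5L) {
  V <- ncol(Z)
  decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), k) %*%
      t(e$vectors) %*% W
  }
  for (attempt in seq_len(restarts)) {
    withr::with_seed(derive_seed(seed, 7919L * (attempt - 1L)), {
      W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
    })
    converged <- FALSE
    damp <- FALSE
    W_prev2 <- NULL
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      Gz <- tanh(alpha * WZ)
      W1 <- Gz %*% t(Z) / V - diag(alpha * rowMeans(1 - Gz^2), k) %*% W
      W1 <- decorrelate(W1)
      if (damp) {
        sgn <- sign(diag(W1 %*% t(W)))
        sgn[sgn == 0] <- 1
        W1 <- decorrelate(0.5 * diag(sgn, k) %*% W1 + 0.5 * W)
      }
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      if (!is.null(W_prev2) && !damp) {
        delta2 <- max(abs(abs(diag(W1 %*% t(W_prev2))) - 1))
        # 2-cycle detected, or stalled for a third of the budget
        if ((delta2 < tol && delta >= tol) || it >= max_iter / 3) damp <- TRUE
      }
      W_prev2 <- W
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) return(list(W = W, iterations = it, attempt = attempt))
  }
  stop(sprintf("FastICA did not converge in %d restarts of %d iterations",
               restarts, max_iter))
}

#' Fit spatial ICA on group-reduced data
#'
#' Estimates `model_order` spatially independent component maps from the
#' group-reduced data by a symmetric FastICA fixed-point iteration (log-cosh
#' contrast) over the voxel dimension. Components are sign-fixed so each
#' map's largest-magnitude voxel is positive, ordered by explained variance,
#' and z-scaled over voxels. Deterministic given the seed.
#'
#' @param reduced An `ica_reduction` from [reduce_two_step()].
#' @param model_order Number of components (<= `group_dim`).
#' @param seed Integer seed for the random orthonormal initialisation.
#' @param alpha Log-cosh contrast slope in [1, 2].
#' @param max_iter,tol,restarts Fixed-point iteration controls.
#' @return An object of class `ica_decomposition`: z-scaled `group_maps`
#'   (`k x voxels`), `mixing` (`group_dim x k`), `unmixing` (`k x group_dim`),
#'   the z-scaling parameters, and fit metadata.
#' @export
fit_spatial_ica <- function(reduced, model_order, seed = 1L, alpha = 1,
                            max_iter = 500L, tol = 1e-7, restarts = 5L) {
  stopifnot(inherits(reduced, "ica_reduction"), is_count(model_order))
  k <- as.integer(model_order)
  if (k > reduced$group_dim)
    stop(sprintf("model_order %d exceeds group_dim %d", k, reduced$group_dim))
  X <- reduced$X
  V <- ncol(X)
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  sv <- svd(Xc)
  if (sv$d[k] <= sv$d[1] * 1e-12)
    stop("group-reduced data are rank deficient at this model order")
  K <- sqrt(V) * diag(1 / sv$d[seq_len(k)], k) %*% t(sv$u[, seq_len(k), drop = FALSE])
  Z <- K %*% Xc  # k x V, rows uncorrelated with unit variance
  fit <- fastica_core(Z, k, seed, alpha, max_iter, tol, restarts)
  unmixing <- fit$W %*% K                       # k x group_dim (applies to centred X)
  S <- unmixing %*% X - drop(unmixing %*% rm_)  # == W Z
  mixing <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] / sqrt(V), k) %*% t(fit$W)  # group_dim x k
  # order by explained variance (rows of S have unit variance)
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  unmixing <- unmixing[ord, , drop = FALSE]
  # sign: peak-magnitude voxel positive
  flip <- vapply(seq_len(k), function(c) {
    v <- S[c, ]; if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  S <- S * flip
  mixing <- sweep(mixing, 2L, flip, "*")
  unmixing <- unmixing * flip
  mu <- rowMeans(S)
  sdv <- sqrt(rowMeans((S - mu)^2) * V / (V - 1))
  structure(list(model_order = k,
                 group_maps = (S - mu) / sdv,
                 mixing = mixing, unmixing = unmixing,
                 scale = list(mu = mu, sd = sdv),
                 seed = seed, iterations = fit$iterations,
                 restarts_used = fit$attempt,
                 explained_variance = colSums(mixing^2)),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> order %d, converged in %d iterations (attempt %d)\n",
              x$model_order, x$iterations, x$restarts_used))
  invisible(x)
}

#' GICA3 back-reconstruction of subject maps and time courses
#'
#' Projects each subject's reduced data through the group unmixing solution.
#' Subject maps are scaled so that their mean across subjects equals the
#' group map exactly (the defining GICA3 consistency property); subject time
#' courses are the back-projection of the mixing matrix through the subject
#' and group PCA bases.
#'
#' @param decomp An `ica_decomposition`.
#' @param reduced The `ica_reduction` the decomposition was fitted on.
#' @return List with `subject_maps` (list of `k x voxels` matrices, z-scaled
#'   like the group maps), `timecourses` (list of `n_scans x k` matrices),
#'   `groups`, and `subject_ids`.
#' @export
back_reconstruct_gica3 <- function(decomp, reduced) {
  stopifnot(inherits(decomp, "ica_decomposition"),
            inherits(reduced, "ica_reduction"))
  if (is.null(reduced$G) || is.null(reduced$Y) || is.null(reduced$subjects))
    stop("reduction object is missing projection metadata")
  N <- reduced$n_subjects
  d1 <- reduced$subject_dim
  k <- decomp$model_order
  U_nm <- decomp$unmixing
  rm_ <- rowMeans(reduced$X)
  offset <- drop(U_nm %*% rm_)
  maps <- tcs <- vector("list", N)
  for (i in seq_len(N)) {
    rows <- (i - 1L) * d1 + seq_len(d1)
    G_i <- reduced$G[rows, , drop = FALSE]        # d1 x group_dim
    Y_i <- reduced$Y[rows, , drop = FALSE]        # d1 x voxels
    S_i <- N * (U_nm %*% crossprod(G_i, Y_i)) - offset
    maps[[i]] <- (S_i - decomp$scale$mu) / decomp$scale$sd
    tc <- reduced$subjects[[i]]$U %*% G_i %*% decomp$mixing  # n_scans x k
    colnames(tc) <- sprintf("IC%d", seq_len(k))
    tcs[[i]] <- tc
  }
  names(maps) <- names(tcs) <- reduced$subject_ids
  list(subject_maps = maps, timecourses = tcs, groups = reduced$groups,
       subject_ids = reduced$subject_ids)
}

#' Greedy matching of components between two decompositions
#'
#' Pairs components by absolute spatial correlation, largest first, keeping
#' matches at or above the threshold.
#'
#' @param maps_a,maps_b `k x voxels` matrices of component maps.
#' @param threshold Minimum absolute correlation for a match.
#' @return Data frame with `a`, `b`, and `abs_cor` per matched pair.
#' @export
match_components <- function(maps_a, maps_b, threshold = 0.7) {
  cm <- abs(cor(t(maps_a), t(maps_b)))
  out <- NULL
  repeat {
    if (all(is.na(cm))) break
    best <- max(cm, na.rm = TRUE)
    if (best < threshold) break
    ij <- which(cm == best, arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(a = unname(ij[1]), b = unname(ij[2]),
                                 abs_cor = best))
    cm[ij[1], ] <- NA; cm[, ij[2]] <- NA
  }
  out %||% data.frame(a = integer(0), b = integer(0), abs_cor = numeric(0))
}

#' Fit spatial ICA over a range of model orders
#'
#' One decomposition per order, with components matched across orders by
#' absolute spatial correlation against the highest-order fit (greedy,
#' threshold 0.7 by default). The per-component stability score is the mean
#' match correlation across the orders where the component was matched;
#' stimulus-locked networks recur across orders while noise components do
#' not.
#'
#' @param reduced An `ica_reduction`.
#' @param orders Integer vector of model orders.
#' @param seed Integer seed (each order derives its own substream).
#' @param threshold Matching threshold on absolute spatial correlation.
#' @param ... Passed to [fit_spatial_ica()].
#' @return List with `fits` (named by order), `reference_order`, `matches`
#'   (per non-reference order), and `stability` per reference component.
#' @export
scan_model_orders <- function(reduced, orders, seed = 1L, threshold = 0.7,
                              ...) {
  stopifnot(length(orders) >= 1L)
  orders <- as.integer(sort(unique(orders)))
  fits <- lapply(seq_along(orders), function(i)
    fit_spatial_ica(reduced, orders[i], seed = derive_seed(seed, 13L * i), ...))
  names(fits) <- as.character(orders)
  ref <- as.character(max(orders))
  ref_maps <- fits[[ref]]$group_maps
  k_ref <- nrow(ref_maps)
  others <- setdiff(names(fits), ref)
  matches <- lapply(others, function(o)
    match_components(ref_maps, fits[[o]]$group_maps, threshold))
  names(matches) <- others
  stability <- vapply(seq_len(k_ref), function(c) {
    cs <- vapply(matches, function(m) {
      hit <- m$abs_cor[m$a == c]
      if (length(hit)) hit[1] else NA_real_
    }, 0)
    if (all(is.na(cs))) NA_real_ else mean(cs, na.rm = TRUE)
  }, 0)
  list(fits = fits, reference_order = as.integer(ref), matches = matches,
       stability = stability)
}

#' Profile component engagement across boundary lags
#'
#' For every component, regresses each subject's component time course
#' jointly on all lagged (HRF-convolved) boundary regressors — the same
#' design the voxelwise GLM uses, so the heavily overlapping lagged
#' regressors do not each absorb the shared variance — and tests the
#' per-lag partial betas against zero across subjects with a one-sample
#' Wilcoxon signed-rank test. A component is classified `"early"` when its
#' minimum-p lag is -1 (engaged before the boundary), `"transition"` when 0
#' or +1 (at or after the boundary; ties broken toward lag 0), and
#' `"unrelated"` when no lag is significant at `alpha`.
#'
#' @param timecourses List of `n_scans x k` subject time-course matrices.
#' @param lagged_regressors `n_scans x n_lags` matrix of lagged regressors
#'   with lags in the column order of `lags`.
#' @param lags Integer lags matching the columns.
#' @param alpha Significance level for the classification rule.
#' @return An object of class `lag_profile`: `table` (component, lag,
#'   median beta, signed-rank statistic, p) and `classification` per
#'   component.
#' @export
profile_lag_significance <- function(timecourses, lagged_regressors,
                                     lags = c(-1L, 0L, 1L), alpha = 0.05) {
  stopifnot(is.list(timecourses), length(timecourses) >= 6L)
  lagged_regressors <- as.matrix(lagged_regressors)
  stopifnot(ncol(lagged_regressors) == length(lags))
  k <- ncol(timecourses[[1]])
  X <- cbind(1, lagged_regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("lagged regressors are collinear")
  # per-subject partial betas: lags x components, NA columns for constant TCs
  beta_list <- lapply(timecourses, function(tc) {
    B <- qr.coef(qx, tc)[-1L, , drop = FALSE]
    const <- apply(tc, 2L, sd) == 0
    if (any(const)) {
      warning("constant component time course excluded from lag profile")
      B[, const] <- NA_real_
    }
    B
  })
  rows <- list()
  classification <- character(k)
  for (c in seq_len(k)) {
    pvals <- numeric(length(lags))
    for (li in seq_along(lags)) {
      betas <- vapply(beta_list, function(B) B[li, c], 0)
      betas <- betas[!is.na(betas)]
      wt <- wilcoxon_signed_rank(betas)
      pvals[li] <- wt$p_two
      rows[[length(rows) + 1L]] <-
        data.frame(component = c, lag = lags[li],
                   median_beta = stats::median(betas),
                   statistic = wt$statistic, p = wt$p_two)
    }
    if (all(pvals >= alpha)) {
      classification[c] <- "unrelated"
    } else {
      pref <- order(pvals, match(lags, c(0L, 1L, -1L)))  # ties toward lag 0
      best <- lags[pref[1]]
      classification[c] <- if (best == -1L) "early" else "transition"
    }
  }
  structure(list(table = do.call(rbind, rows),
                 classification = classification, alpha = alpha, lags = lags),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("<lag_profile> %d components at alpha = %g: %s\n",
              length(x$classification), x$alpha,
              paste(sprintf("IC%d=%s", seq_along(x$classification),
                            x$classification), collapse = ", ")))
  invisible(x)
}

#' Compare subject component maps between groups, cluster-corrected
#'
#' Voxelwise two-sample rank-based comparison of subject-specific component
#' map weights between groups, with cluster-extent FWE correction by
#' label-shuffle permutation.
#'
#' @param subject_maps List of `k x voxels` subject map matrices (as from
#'   [back_reconstruct_gica3()]), or a `subjects x voxels` matrix for a
#'   single component.
#' @param groups Group label per subject.
#' @param mask Logical 3-D array.
#' @param component Component index when `subject_maps` is a list.
#' @param forming_p Cluster-forming threshold (0.05 follows the group-map
#'   convention for component comparisons).
#' @param n_permutations,seed,connectivity Passed to [cluster_correct()].
#' @return A `cluster_result` (with the voxelwise `group_map` in `$stat`).
#' @export
compare_groups_ica <- function(subject_maps, groups, mask, component = 1L,
                               forming_p = 0.05, n_permutations = 1000L,
                               seed = 1L, connectivity = 26L) {
  M <- if (is.list(subject_maps))
    t(vapply(subject_maps, function(m) m[component, ],
             numeric(ncol(subject_maps[[1]]))))
  else as.matrix(subject_maps)
  lev <- sort(unique(groups))
  if (length(lev) != 2L || min(table(groups)) < 2L)
    stop("two groups with at least 2 subjects each are required")
  cluster_correct(M, mask, forming_p = forming_p, scheme = "label_shuffle",
                  groups = groups, n_permutations = n_permutations,
                  seed = seed, connectivity = connectivity)
}
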