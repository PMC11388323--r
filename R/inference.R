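# Nonparametric inference: exact Wilcoxon primitives, Benjamini-Hochberg FDR,
# permutation cluster-extent FWE correction with the max-statistic method,
# and agglomerative clustering of statistic maps.

#' One-sample Wilcoxon signed-rank test
#'
#' Exact null distribution (via the signed-rank distribution) for n <= 25
#' without ties among the absolute deviations; normal approximation with tie
#' correction otherwise. Exact zeros are dropped before ranking.
#'
#' @param values Numeric sample.
#' @param mu0 Null location.
#' @return List with `statistic` (W+, the positive-rank sum), `n` (after
#'   dropping zeros), `p_two`, `p_greater`, `p_less`, `z`, and `exact`.
#' @export
wilcoxon_signed_rank <- function(values, mu0 = 0) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, n = 0L, p_two = 1, p_greater = 1, p_less = 1,
                z = 0, exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25L) {
    p_greater <- 1 - psignrank(W - 1, n)
    p_less <- psignrank(W, n)
    list(statistic = W, n = n, p_two = min(1, 2 * min(p_greater, p_less)),
         p_greater = p_greater, p_less = p_less,
         z = (W - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24),
         exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(max(sig2, .Machine$double.eps))
    if (sig2 == 0) z <- 0
    list(statistic = W, n = n, p_two = min(1, 2 * pnorm(-abs(z))),
         p_greater = pnorm(z, lower.tail = FALSE), p_less = pnorm(z),
         z = z, exact = FALSE)
  }
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact null (via the Mann-Whitney distribution) without ties when both
#' samples have at most 25 observations; mid-ranks with a tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p_two`,
#'   `p_greater`, `p_less`, `z`, and `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  N <- n1 + n2
  mu <- n1 * n2 / 2
  if (!ties && max(n1, n2) <= 25L) {
    p_greater <- 1 - pwilcox(U - 1, n1, n2)
    p_less <- pwilcox(U, n1, n2)
    list(statistic = U, p_two = min(1, 2 * min(p_greater, p_less)),
         p_greater = p_greater, p_less = p_less,
         z = (U - mu) / sqrt(n1 * n2 * (N + 1) / 12), exact = TRUE)
  } else {
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
    list(statistic = U, p_two = if (sig2 > 0) min(1, 2 * pnorm(-abs(z))) else 1,
         p_greater = pnorm(z, lower.tail = FALSE), p_less = pnorm(z),
         z = z, exact = FALSE)
  }
}

# Vectorised voxelwise rank-sum over columns: A, B are subjects x voxels.
rank_sum_map <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B); N <- n1 + n2
  M <- rbind(A, B)
  R <- col_ranks(M)
  W <- colSums(R[seq_len(n1), , drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- apply(R, 2L, function(r) { tt <- table(r); sum(tt^3 - tt) })
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- ifelse(sig2 > 0, (U - mu) / sqrt(pmax(sig2, .Machine$double.eps)), 0)
  p <- numeric(length(U))
  exact_ok <- tie_term == 0 & max(n1, n2) <= 25L
  if (any(exact_ok)) {
    pg <- 1 - pwilcox(U[exact_ok] - 1, n1, n2)
    pl <- pwilcox(U[exact_ok], n1, n2)
    p[exact_ok] <- pmin(1, 2 * pmin(pg, pl))
  }
  if (any(!exact_ok))
    p[!exact_ok] <- ifelse(sig2[!exact_ok] > 0,
                           pmin(1, 2 * pnorm(-abs(z[!exact_ok]))), 1)
  list(u = U, z = z, p = p)
}

# Vectorised one-sample signed-rank over columns of D (subjects x voxels).
signed_rank_map <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clean <- colSums(D == 0) == 0L
  no_tie <- apply(abs(D), 2L, anyDuplicated) == 0L
  fast <- clean & no_tie & n <= 25L
  z <- p <- W <- numeric(ncol(D))
  if (any(fast)) {
    R <- col_ranks(abs(D[, fast, drop = FALSE]))
    Wf <- colSums(R * (D[, fast, drop = FALSE] > 0))
    pg <- 1 - psignrank(Wf - 1, n)
    pl <- psignrank(Wf, n)
    W[fast] <- Wf
    p[fast] <- pmin(1, 2 * pmin(pg, pl))
    z[fast] <- (Wf - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  }
  for (j in which(!fast)) {
    res <- wilcoxon_signed_rank(D[, j])
    W[j] <- res$statistic; p[j] <- res$p_two; z[j] <- res$z
  }
  list(w = W, z = z, p = p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p_values Numeric p-values in [0, 1].
#' @return Adjusted p-values (step-up rule), order-preserving and never below
#'   the raw values.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

# 26- or 6-connected component labelling of a set of voxels given by linear
# indices into a 3-D grid. Returns an integer cluster label per input voxel.
label_clusters <- function(idx_lin, dim3, connectivity = 26L) {
  k <- length(idx_lin)
  if (k == 0L) return(integer(0))
  if (k == 1L) return(1L)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1L, ]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  offs <- offs[seq_len(nrow(offs) / 2L), , drop = FALSE]  # half-neighbourhood
  lab <- array(0L, dim = dim3)
  lab[idx_lin] <- seq_len(k)
  co <- arrayInd(idx_lin, dim3)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nx <- co[, 1] + offs$dx[o]; ny <- co[, 2] + offs$dy[o]; nz <- co[, 3] + offs$dz[o]
    ok <- nx >= 1L & nx <= dim3[1] & ny >= 1L & ny <= dim3[2] & nz >= 1L & nz <= dim3[3]
    if (!any(ok)) next
    nb <- lab[cbind(nx[ok], ny[ok], nz[ok])]
    hit <- nb > 0L
    if (any(hit)) {
      pairs_a <- c(pairs_a, which(ok)[hit])
      pairs_b <- c(pairs_b, nb[hit])
    }
  }
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_along(pairs_a)) {
    ra <- find(pairs_a[e]); rb <- find(pairs_b[e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(k), find, 0L)
  match(roots, unique(roots))
}

#' Permutation cluster-extent family-wise error correction
#'
#' Computes a voxelwise statistic from subject-level maps (one-sample t for
#' the sign-flip scheme, Wilcoxon rank-sum z for the label-shuffle two-sample
#' scheme), thresholds it at an uncorrected cluster-forming p-value, labels
#' suprathreshold voxels into connected components (positive and negative
#' tails separately), and corrects cluster extents against the permutation
#' null distribution of the maximum cluster extent (strong FWE control by
#' the max-statistic method, add-one estimator).
#'
#' @param subject_maps Numeric matrix `subjects x voxels` of subject-level
#'   statistics.
#' @param mask Logical 3-D array whose in-mask voxels correspond to columns.
#' @param forming_p Uncorrected two-sided cluster-forming threshold in (0,1).
#' @param scheme `"sign_flip"` (one-sample) or `"label_shuffle"` (two-sample).
#' @param groups Group labels, required for `"label_shuffle"`.
#' @param n_permutations Number of permutations (warning below 100).
#' @param seed Integer seed for the permutation draws.
#' @param connectivity Voxel neighbourhood, 26 (default) or 6.
#' @return An object of class `cluster_result`: `table` (a `ClusterTable`
#'   data frame with `cluster_id`, `extent`, `peak_stat`, `peak_x/y/z`
#'   (0-based voxel indices), `sign`, `corrected_p`), the observed `stat` and
#'   `p` maps, and `null_max_extent`.
#' @export
cluster_correct <- function(subject_maps, mask, forming_p = 0.001,
                            scheme = c("sign_flip", "label_shuffle"),
                            groups = NULL, n_permutations = 1000L, seed = 1L,
                            connectivity = 26L) {
  scheme <- match.arg(scheme)
  subject_maps <- as.matrix(subject_maps)
  if (!(forming_p > 0 && forming_p < 1)) stop("forming_p must lie in (0, 1)")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations: corrected p-values are coarse")
  n <- nrow(subject_maps); V <- ncol(subject_maps)
  stopifnot(sum(mask) == V)
  dim3 <- dim(mask)
  m_lin <- which(mask)

  if (scheme == "sign_flip") {
    ssq <- colSums(subject_maps^2)
    stat_fun <- function(signs) {
      mean_ <- as.vector(signs %*% subject_maps) / n
      v <- pmax((ssq - n * mean_^2) / (n - 1), 0)
      t <- mean_ / sqrt(v / n)
      t[v == 0] <- 0
      t
    }
    obs <- stat_fun(matrix(1, 1L, n))
    p_obs <- 2 * pt(-abs(obs), df = n - 1)
    withr::with_seed(derive_seed(seed, 0L), {
      S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
    })
    perm_stat <- S %*% subject_maps / n
    vmat <- pmax(sweep(-n * perm_stat^2, 2L, ssq, "+") / (n - 1), 0)
    perm_t <- perm_stat / sqrt(vmat / n)
    perm_t[vmat == 0] <- 0
    perm_p <- 2 * pt(-abs(perm_t), df = n - 1)
    get_perm <- function(i) list(stat = perm_t[i, ], p = perm_p[i, ])
  } else {
    if (is.null(groups)) stop("label_shuffle scheme requires group labels")
    lev <- sort(unique(groups))
    if (length(lev) != 2L) stop("label_shuffle scheme requires exactly two groups")
    n1 <- sum(groups == lev[1])
    R <- col_ranks(subject_maps)
    tie_term <- apply(R, 2L, function(r) { tt <- table(r); sum(tt^3 - tt) })
    N <- n
    sig2 <- n1 * (N - n1) / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    mu <- n1 * (N - n1) / 2
    z_from_idx <- function(ind) {
      W <- as.vector(ind %*% R)
      U <- W - n1 * (n1 + 1) / 2
      z <- ifelse(sig2 > 0, (U - mu) / sqrt(pmax(sig2, .Machine$double.eps)), 0)
      z
    }
    ind_obs <- matrix(as.numeric(groups == lev[1]), 1L, n)
    obs <- z_from_idx(ind_obs)
    p_obs <- 2 * pnorm(-abs(obs))
    withr::with_seed(derive_seed(seed, 0L), {
      Ind <- t(vapply(seq_len(n_permutations), function(i) {
        v <- numeric(n); v[sample.int(n, n1)] <- 1; v
      }, numeric(n)))
    })
    perm_z <- {
      W <- Ind %*% R
      U <- W - n1 * (n1 + 1) / 2
      sweep(U, 2L, mu, "-") / rep(sqrt(pmax(sig2, .Machine$double.eps)),
                                  each = n_permutations)
    }
    perm_z[, sig2 == 0] <- 0
    perm_p <- 2 * pnorm(-abs(perm_z))
    get_perm <- function(i) list(stat = perm_z[i, ], p = perm_p[i, ])
  }

  cluster_extents <- function(stat, p) {
    supra <- which(p < forming_p)
    if (!length(supra)) return(NULL)
    out <- list()
    for (sgn in c(1, -1)) {
      side <- supra[sign(stat[supra]) == sgn]
      if (!length(side)) next
      labs <- label_clusters(m_lin[side], dim3, connectivity)
      for (cl in unique(labs)) {
        vox <- side[labs == cl]
        out[[length(out) + 1L]] <- list(vox = vox, sign = sgn,
                                        extent = length(vox))
      }
    }
    out
  }

  obs_clusters <- cluster_extents(obs, p_obs)
  null_max <- vapply(seq_len(n_permutations), function(i) {
    pp <- get_perm(i)
    cls <- cluster_extents(pp$stat, pp$p)
    if (is.null(cls)) 0L else max(vapply(cls, `[[`, 0L, "extent"))
  }, 0L)

  tab <- if (is.null(obs_clusters)) {
    data.frame(cluster_id = integer(0), extent = integer(0),
               peak_stat = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0),
               sign = integer(0), corrected_p = numeric(0))
  } else {
    rows <- lapply(seq_along(obs_clusters), function(i) {
      cl <- obs_clusters[[i]]
      pk <- cl$vox[which.max(abs(obs[cl$vox]))]
      co <- arrayInd(m_lin[pk], dim3) - 1L  # 0-based voxel indices
      data.frame(cluster_id = i, extent = cl$extent, peak_stat = obs[pk],
                 peak_x = co[1], peak_y = co[2], peak_z = co[3],
                 sign = cl$sign,
                 corrected_p = (1 + sum(null_max >= cl$extent)) /
                   (n_permutations + 1))
    })
    do.call(rbind, rows[order(-vapply(obs_clusters, `[[`, 0L, "extent"))])
  }
  if (nrow(tab)) tab$cluster_id <- seq_len(nrow(tab))
  structure(list(table = tab, stat = obs, p = p_obs,
                 null_max_extent = null_max, forming_p = forming_p,
                 scheme = scheme, n_permutations = n_permutations,
                 connectivity = connectivity),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, forming p < %g, %d permutations: %d cluster(s)\n",
              x$scheme, x$forming_p, x$n_permutations, nrow(x$table)))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Agglomerative hierarchical clustering of statistic maps
#'
#' Pairwise distances are one minus the Pearson correlation over in-mask
#' voxels; merging uses average (default) or complete linkage. Used to ask
#' which lag maps resemble each other (e.g. whether the at-boundary and
#' post-boundary maps group together, apart from the pre-boundary map).
#'
#' @param maps Numeric matrix `maps x voxels` (rows named by lag) or list of
#'   equal-length vectors.
#' @param linkage `"average"` or `"complete"`.
#' @return An object of class `linkage_result`: the `hclust` fit, the
#'   `merge_sequence` data frame, and `labels2` (the two-cluster partition).
#' @export
cluster_lag_maps <- function(maps, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (is.list(maps)) maps <- do.call(rbind, maps)
  stopifnot(is.matrix(maps), nrow(maps) >= 3L)
  if (any(apply(maps, 1L, sd) == 0))
    stop("constant map: correlation distance undefined")
  d <- as.dist(1 - cor(t(maps)))
  h <- hclust(d, method = linkage)
  merges <- data.frame(step = seq_len(nrow(h$merge)),
                       a = h$merge[, 1], b = h$merge[, 2],
                       height = h$height)
  structure(list(hclust = h, merge_sequence = merges,
                 labels2 = cutree(h, k = 2L), linkage = linkage,
                 distance = "one_minus_pearson"),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> %s linkage on 1 - Pearson distance, %d items\n",
              x$linkage, length(x$hclust$labels %||% x$labels2)))
  print(x$merge_sequence, row.names = FALSE)
  invisible(x)
}

#' First items merged by a linkage result
#'
#' @param x A `linkage_result`.
#' @return Character or integer vector of the two singleton items joined at
#'   the first merge (NA entries if the first merge involves a cluster).
#' @export
first_merge <- function(x) {
  stopifnot(inherits(x, "linkage_result"))
  m <- x$hclust$merge[1, ]
  items <- ifelse(m < 0, -m, NA_integer_)
  if (!is.null(x$hclust$labels)) x$hclust$labels[items] else items
}
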