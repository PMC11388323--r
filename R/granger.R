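# Difference-of-influence Granger causality between two component time
# courses: bivariate VAR order selection by AIC/BIC, Geweke-style log
# variance-ratio influence measures, and group inference on per-subject
# difference-of-influence values. The DOI statistic (F_{x->y} - F_{y->x})
# counters the spurious bidirectionality that low temporal resolution and
# haemodynamic blurring induce in fMRI signals.

lag_block <- function(s, p, n) {
  # columns s[t-1], ..., s[t-p] for t = (p+1):n
  vapply(seq_len(p), function(j) s[(p + 1 - j):(n - j)], numeric(n - p))
}

#' Select the VAR model order by AIC and BIC
#'
#' Fits a bivariate VAR by OLS for each order `1..max_order` on the common
#' sample (so criteria are comparable) and returns the AIC and BIC
#' minimizers. Near-singular fits are skipped with a warning.
#'
#' @param x,y Numeric scan series.
#' @param max_order Largest order tried.
#' @return List with `order_aic`, `order_bic`, and the criterion `table`.
#' @export
select_var_order <- function(x, y, max_order = 10L) {
  stopifnot(is_count(max_order))
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n <= 3L * max_order)
    stop("series length must exceed 3 * max_order")
  x <- as.numeric(scale(x)); y <- as.numeric(scale(y))
  tt <- (max_order + 1L):n  # common sample across orders
  n_eff <- length(tt)
  Yresp <- cbind(x[tt], y[tt])
  aic <- bic <- rep(NA_real_, max_order)
  for (p in seq_len(max_order)) {
    X <- cbind(1, lag_block(x, p, n)[tt - p, , drop = FALSE],
               lag_block(y, p, n)[tt - p, , drop = FALSE])
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning(sprintf("order %d skipped: near-singular regression", p))
      next
    }
    res <- qr.resid(qx, Yresp)
    Sigma <- crossprod(res) / n_eff
    ld <- determinant(Sigma, logarithm = TRUE)
    if (ld$sign <= 0) {
      warning(sprintf("order %d skipped: degenerate residual covariance", p))
      next
    }
    k_par <- 2 * (2 * p + 1)
    aic[p] <- n_eff * as.numeric(ld$modulus) + 2 * k_par
    bic[p] <- n_eff * as.numeric(ld$modulus) + log(n_eff) * k_par
  }
  if (all(is.na(aic))) stop("no VAR order could be fitted")
  list(order_aic = which.min(aic), order_bic = which.min(bic),
       table = data.frame(order = seq_len(max_order), aic = aic, bic = bic))
}

#' Granger influence measures between two series
#'
#' `f_xy` is the log ratio of the residual variance of y's restricted
#' autoregression (own lags only) to that of the full regression (own plus
#' x lags), both fitted by OLS on the same sample window; `f_yx` is the
#' symmetric quantity. Both are invariant to rescaling either series;
#' series are variance-normalized before fitting for numerical stability.
#'
#' @param x,y Numeric scan series.
#' @param order VAR order (number of lags).
#' @return List with `f_xy` and `f_yx`.
#' @export
granger_influence <- function(x, y, order) {
  stopifnot(is_count(order))
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n <= 3L * order) stop("series length must exceed 3 * order")
  x <- as.numeric(scale(x)); y <- as.numeric(scale(y))
  p <- as.integer(order)
  Xl <- lag_block(x, p, n); Yl <- lag_block(y, p, n)
  rss <- function(resp, Xmat) {
    r <- qr.resid(qr(cbind(1, Xmat)), resp)
    sum(r^2)
  }
  resp_y <- y[(p + 1):n]; resp_x <- x[(p + 1):n]
  rss_y_full <- rss(resp_y, cbind(Yl, Xl))
  rss_y_restr <- rss(resp_y, Yl)
  rss_x_full <- rss(resp_x, cbind(Xl, Yl))
  rss_x_restr <- rss(resp_x, Xl)
  if (min(rss_y_full, rss_x_full) <= 0)
    stop("zero residual variance: series are deterministic at this order")
  list(f_xy = log(rss_y_restr / rss_y_full),
       f_yx = log(rss_x_restr / rss_x_full))
}

#' Difference of influence
#'
#' `doi(x, y) = f_xy - f_yx`; positive values indicate net directed
#' influence from `x` to `y`. Exactly antisymmetric in its arguments.
#'
#' @inheritParams granger_influence
#' @return A single numeric value.
#' @export
doi <- function(x, y, order) {
  f <- granger_influence(x, y, order)
  f$f_xy - f$f_yx
}

#' Per-subject Granger analysis of a component pair
#'
#' Convenience wrapper: selects the VAR order (AIC by default, BIC recorded
#' alongside) and computes the influence measures and DOI for one subject's
#' pair of component time courses.
#'
#' @param x,y Numeric component time courses.
#' @param max_order Largest order tried in selection.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param subject_id Optional identifier.
#' @return An object of class `granger_result`.
#' @export
granger_subject <- function(x, y, max_order = 10L,
                            criterion = c("aic", "bic"),
                            subject_id = NA_character_) {
  criterion <- match.arg(criterion)
  sel <- select_var_order(x, y, max_order)
  ord <- if (criterion == "aic") sel$order_aic else sel$order_bic
  f <- granger_influence(x, y, ord)
  structure(list(subject_id = subject_id, order_aic = sel$order_aic,
                 order_bic = sel$order_bic, order_used = ord,
                 f_xy = f$f_xy, f_yx = f$f_yx, doi = f$f_xy - f$f_yx),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> %s: order %d (AIC %d / BIC %d), f_xy = %.4f, f_yx = %.4f, doi = %+.4f\n",
              x$subject_id, x$order_used, x$order_aic, x$order_bic,
              x$f_xy, x$f_yx, x$doi))
  invisible(x)
}

#' Group inference on per-subject difference-of-influence values
#'
#' One-sample Wilcoxon signed-rank test of the subject DOIs against zero,
#' with Benjamini-Hochberg adjustment across network pairs when several are
#' tested. The causal direction is set by the sign of the median DOI when
#' the adjusted p-value falls below `alpha`, else `"undetermined"`.
#'
#' @param dois Numeric vector of per-subject DOI values (one network pair),
#'   or a list of such vectors (several pairs) or of `granger_result`s.
#' @param alpha Significance level (the source analyses use 0.0001).
#' @return A `group_granger_test` (or a list of them, one per pair): fields
#'   `statistic`, `p_raw`, `p_fdr`, `median_doi`, `direction`, `n`.
#' @export
group_doi_test <- function(dois, alpha = 1e-4) {
  as_pairs <- if (is.list(dois) && !is.numeric(dois[[1]])) {
    list(vapply(dois, function(r) r$doi, 0))
  } else if (is.list(dois)) dois else list(dois)
  tests <- lapply(as_pairs, function(d) {
    if (length(d) < 6L) {
      warning("fewer than 6 subjects: direction undetermined")
      return(list(statistic = NA_real_, p_raw = NA_real_, n = length(d),
                  median_doi = stats::median(d)))
    }
    wt <- wilcoxon_signed_rank(d)
    list(statistic = wt$statistic, p_raw = wt$p_two, n = wt$n,
         median_doi = stats::median(d))
  })
  p_fdr <- fdr_adjust(vapply(tests, function(t) t$p_raw, 0))
  out <- lapply(seq_along(tests), function(i) {
    t <- tests[[i]]
    dir <- if (is.na(t$p_raw) || p_fdr[i] >= alpha) "undetermined"
    else if (t$median_doi > 0) "x_causes_y" else "y_causes_x"
    structure(c(t, list(p_fdr = p_fdr[i], direction = dir, alpha = alpha)),
              class = "group_granger_test")
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @export
print.group_granger_test <- function(x, ...) {
  cat(sprintf("<group_granger_test> n = %d, W = %s, p = %.3g (FDR %.3g), median DOI = %+.4f -> %s\n",
              x$n, format(x$statistic), x$p_raw, x$p_fdr, x$median_doi,
              x$direction))
  invisible(x)
}
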