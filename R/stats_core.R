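#' Normalization and moderated statistics
#'
#' The two-group testing engine shared by the loop and expression
#' analyses. It implements trimmed-mean-of-M-values (TMM)
#' between-sample normalization, a log2 counts-per-million transform,
#' ordinary two-group linear fits and empirical-Bayes variance
#' moderation (scaled-F prior on residual variances, prior degrees of
#' freedom recovered by inverting the trigamma function), followed by
#' Benjamini-Hochberg adjustment. Values need not be integer counts:
#' continuous nonnegative loop strengths are accepted directly, with
#' library size defined as the column sum.
#'
#' @name stats_core
NULL

check_count_matrix <- function(m, group = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0)) stop("count matrix has negative entries")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids")
  if (!is.null(group)) {
    if (length(group) != ncol(m)) stop("group length != number of samples")
    tab <- table(group)
    if (length(tab) != 2) stop("exactly two group labels required")
    if (any(tab < 2)) stop("at least 2 samples per group required")
  }
  m
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values against a reference sample. The reference
#' is the sample whose upper-quartile/library-size ratio is closest to
#' the mean of those ratios. For each sample, features with zero value
#' in either the sample or the reference are excluded; the remaining
#' log2 ratios (M) and average log2 abundances (A) are doubly trimmed
#' (`logratio_trim` of M, `abs_trim` of A, both tails) and combined by
#' weights equal to the inverse of the binomial delta-method variance
#' approximation. Factors are rescaled so their geometric mean is 1.
#'
#' @param m nonnegative numeric matrix (features x samples).
#' @param logratio_trim fraction of M-values trimmed from each tail.
#' @param abs_trim fraction of A-values trimmed from each tail.
#' @return list with `lib_size` (column sums) and `tmm_factor`.
#' @export
tmm_factors <- function(m, logratio_trim = 0.30, abs_trim = 0.05) {
  m <- check_count_matrix(m)
  lib <- colSums(m)
  if (any(lib <= 0)) stop("sample with zero library size")
  # reference: upper-quartile/lib ratio closest to the mean ratio
  f75 <- apply(m, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair(m[, j], m[, ref], lib[j], lib[ref],
             logratio_trim, abs_trim)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  list(lib_size = lib, tmm_factor = stats::setNames(fac, colnames(m)))
}

# one sample vs reference; follows the published TMM estimator
tmm_pair <- function(obs, ref, n_o, n_r, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  M <- log2((obs / n_o) / (ref / n_r))
  A <- 0.5 * log2((obs / n_o) * (ref / n_r))
  w <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  fin <- is.finite(M) & is.finite(A) & is.finite(w) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Log2 counts-per-million
#'
#' `log2((count + prior) / (lib_size * tmm_factor) * 1e6)`.
#'
#' @param m nonnegative matrix.
#' @param norm output of [tmm_factors()]; computed when `NULL`.
#' @param prior prior count added before the log (default 0.5 keeps
#'   zeros finite).
#' @return matrix of log2 normalized values.
#' @export
log_cpm <- function(m, norm = NULL, prior = 0.5) {
  m <- check_count_matrix(m)
  if (is.null(norm)) norm <- tmm_factors(m)
  eff <- norm$lib_size * norm$tmm_factor
  log2(sweep(m + prior, 2, eff, "/") * 1e6)
}

row_sd <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

#' Select the most variable features
#'
#' The `n` features with largest row standard deviation (sample SD,
#' denominator n-1). Ties are broken by input order; with fewer than
#' `n` rows all features are returned.
#'
#' @param logm numeric matrix with feature row names.
#' @param n number of features to keep.
#' @return character vector of selected feature ids, in input order.
#' @export
top_variable <- function(logm, n) {
  stopifnot(n >= 1)
  if (is.null(rownames(logm))) rownames(logm) <- as.character(seq_len(nrow(logm)))
  n <- min(n, nrow(logm))
  sds <- row_sd(logm)
  sel <- order(-sds, seq_along(sds))[seq_len(n)]
  rownames(logm)[sort(sel)]
}

#' Two-group linear fit
#'
#' Per-feature group-mean fit: `log_fc` = mean(relapse) -
#' mean(diagnosis), pooled residual variance with `n - 2` degrees of
#' freedom.
#'
#' @param logm matrix of log2 values.
#' @param group per-sample labels with exactly two levels; the
#'   reference (subtracted) level is `ref`.
#' @param ref label treated as baseline (default "diagnosis").
#' @return list with `log_fc`, `ave_expr`, `s2`, `df_resid`, and the
#'   group sizes `n1`, `n2`.
#' @export
fit_two_group <- function(logm, group, ref = "diagnosis") {
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly two group labels required")
  if (!ref %in% lev) ref <- lev[1]
  other <- setdiff(lev, ref)
  i1 <- group == ref; i2 <- group == other
  if (sum(i1) < 2 || sum(i2) < 2) stop("at least 2 samples per group required")
  m1 <- rowMeans(logm[, i1, drop = FALSE])
  m2 <- rowMeans(logm[, i2, drop = FALSE])
  rss <- rowSums((logm[, i1, drop = FALSE] - m1)^2) +
         rowSums((logm[, i2, drop = FALSE] - m2)^2)
  df <- ncol(logm) - 2
  list(log_fc = m2 - m1,
       ave_expr = rowMeans(logm),
       s2 = rss / df,
       df_resid = df,
       n1 = sum(i1), n2 = sum(i2))
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by a monotone Newton
#' iteration on `1/trigamma`.
#'
#' @param y positive value.
#' @return x with `trigamma(x) = y` (to ~1e-8 relative).
#' @export
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Fit a scaled-F prior to residual variances
#'
#' Method-of-moments fit on log variances: matches the mean and
#' variance of `log(s2)` to the digamma/trigamma moments implied by a
#' scaled F distribution with `df_resid` and `d0` degrees of freedom,
#' recovering the prior df `d0` by trigamma inversion and the prior
#' variance `s0_sq`. When the spread of `log(s2)` does not exceed the
#' chi-square sampling spread, `d0` is infinite.
#'
#' @param s2 positive residual variances.
#' @param df_resid residual degrees of freedom.
#' @return list with `d0` and `s0_sq`.
#' @export
fit_f_dist <- function(s2, df_resid) {
  stopifnot(all(s2 > 0), df_resid > 0)
  z <- log(s2)
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df_resid / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # spread of log s2 does not exceed chi-square sampling spread:
    # infinite prior df, prior variance at the mean variance
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-feature variances toward the fitted prior:
#' `s2_post = (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)`.
#' With fewer than 10 positive variances the prior cannot be fitted
#' and full shrinkage to the mean variance is used (`d0 = Inf`).
#'
#' @param s2 residual variances (all >= 0; zeros are an error — apply
#'   a variance floor first, see [moderated_test()]).
#' @param df_resid residual degrees of freedom.
#' @param d0,s0_sq optional fixed prior parameters, bypassing the
#'   fit (`d0 = 0` recovers the unmoderated variances).
#' @return list with `d0`, `s0_sq`, `s2_post`, `df_total`.
#' @export
ebayes_shrink <- function(s2, df_resid, d0 = NULL, s0_sq = NULL) {
  if (all(s2 == 0))
    stop("all residual variances are zero; apply a variance floor ",
         "(e.g. 1e-8) before moderation")
  if (any(s2 < 0)) stop("negative variance")
  pos <- s2 > 0
  if (is.null(d0)) {
    if (sum(pos) < 10) {
      d0 <- Inf; s0_sq <- mean(s2)
    } else {
      fit <- fit_f_dist(s2[pos], df_resid)
      d0 <- fit$d0; s0_sq <- fit$s0_sq
    }
  } else if (is.null(s0_sq)) s0_sq <- mean(s2)
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post,
       df_total = d0 + df_resid)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity
#' enforcement; output is in the input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Moderated two-group test
#'
#' The full per-feature pipeline on a log-scale matrix: two-group
#' fit, empirical-Bayes variance shrinkage (after a variance floor
#' `var_floor` that guards exact duplicates), moderated t with
#' `d0 + df_resid` degrees of freedom, and BH adjustment.
#'
#' With `weight_trend = TRUE` a simplified mean-variance weighting is
#' applied: a running-median trend of the quarter-root variance
#' (sqrt of residual SD) against average log2 abundance is fitted,
#' per-feature weights `trend^-4` standardize the variances before
#' shrinkage, and the moderated t is computed on the unstandardized
#' scale.
#'
#' @param logm matrix of log2 values (features x samples).
#' @param group per-sample two-level labels.
#' @param ref baseline label (log_fc = other - ref).
#' @param weight_trend logical; apply the mean-variance trend
#'   weighting (off by default).
#' @param var_floor lower bound applied to residual variances.
#' @return data.frame with columns feature_id, log_fc, ave_expr, s2,
#'   s2_post, t_mod, p, p_adj; attributes `d0` and `s0_sq`.
#' @export
moderated_test <- function(logm, group, ref = "diagnosis",
                           weight_trend = FALSE, var_floor = 1e-8) {
  fit <- fit_two_group(logm, group, ref = ref)
  s2 <- pmax(fit$s2, var_floor)
  w <- rep(1, length(s2))
  if (weight_trend && length(s2) >= 10) {
    qr_sd <- s2^(1/4)                     # sqrt of residual SD
    o <- order(fit$ave_expr)
    k <- max(3, 2 * floor(length(s2) * 0.05 / 2) + 1)
    k <- min(k, 2 * floor((length(s2) - 1) / 2) + 1)
    trend <- numeric(length(s2))
    trend[o] <- stats::runmed(qr_sd[o], k, endrule = "median")
    trend <- pmax(trend, (var_floor)^(1/4))
    w <- trend^-4                          # inverse predicted variance
  }
  eb <- ebayes_shrink(s2 * w, fit$df_resid)
  s2_post <- eb$s2_post / w
  v <- 1 / fit$n1 + 1 / fit$n2
  t_mod <- fit$log_fc / sqrt(s2_post * v)
  p <- 2 * stats::pt(-abs(t_mod), df = eb$df_total)
  res <- data.frame(feature_id = rownames(logm),
                    log_fc = unname(fit$log_fc),
                    ave_expr = unname(fit$ave_expr),
                    s2 = unname(fit$s2),
                    s2_post = unname(s2_post),
                    t_mod = unname(t_mod),
                    p = unname(p),
                    p_adj = unname(bh_adjust(p)),
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- eb$d0
  attr(res, "s0_sq") <- eb$s0_sq
  attr(res, "df_resid") <- fit$df_resid
  res
}
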