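#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with cumulative-minimum monotonicity,
#' capped at 1; adjusted values follow their p-values under input-order
#' permutation. Thin validated wrapper over `stats::p.adjust`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Newton solve of trigamma(y) = x; x > 0. Standard approach: iterate on
## 1/y where trigamma is approximately 1/y for large y.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes fit of a scaled inverse-chisquare variance prior
#'
#' Moment-matches the prior degrees of freedom `df_prior` and prior
#' variance `s2_prior` to an ensemble of residual variances with common
#' residual df, using the distribution of log sample variances: with
#' e_g = log(s_g^2) - digamma(d/2) + log(d/2), the excess of var(e) over
#' trigamma(d/2) identifies trigamma(d0/2), inverted numerically. When
#' the observed variances are at least as homogeneous as sampling alone
#' predicts the estimator diverges; `df_prior` is then set to a large
#' finite cap (10^7) with a warning.
#'
#' @param s2 per-feature residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `df_prior` and `s2_prior`.
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(df >= 1)
  pos <- s2 > 0
  if (sum(pos) < 2) {
    warning("too few positive variances to fit a prior; using a diffuse cap")
    return(list(df_prior = 1e7,
                s2_prior = if (any(pos)) mean(s2[pos]) else 1e-8))
  }
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    warning("variances homogeneous; prior df capped at 1e7")
    df_prior <- 1e7
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Moderated-t differential expression between two groups
#'
#' Per feature, fits the two-group mean model on log2 expression
#' (log2(TPM + 1) is the intended input scale), computes the pooled
#' residual variance s^2 with d = n1 + n2 - 2 df, shrinks it toward an
#' empirical-Bayes prior estimated from the whole ensemble,
#' s2_post = (d0 s0^2 + d s^2) / (d0 + d), and tests
#' t = logFC / sqrt(s2_post (1/n1 + 1/n2)) on d0 + d degrees of freedom.
#' P-values are BH-adjusted across all tested features. logFC is
#' mean(level 2) - mean(level 1) of `groups`.
#'
#' @param expr numeric matrix (features x samples) on the log2 scale, or
#'   a `NormalizedMatrix` (then transformed as log2(values + 1)).
#' @param groups two-level factor (or coercible) along the columns;
#'   each level needs >= 2 samples.
#' @param df_prior,s2_prior optional forced prior; `df_prior = 0` yields
#'   the ordinary pooled t, `df_prior = Inf` uses `s2_prior` exactly.
#'   Both default to the [fit_variance_prior()] estimate.
#' @return data.frame with `feature_id`, `logFC`, `t_mod`, `p`, `fdr`,
#'   `mean_<level1>`, `mean_<level2>`, `s2`, `s2_post`; attributes
#'   `df_prior`, `s2_prior`, `df_residual`.
#' @export
moderated_t_de <- function(expr, groups, df_prior = NULL, s2_prior = NULL) {
  if (is(expr, "NormalizedMatrix")) expr <- log2(expr$values + 1)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (length(groups) != ncol(expr)) stop("groups length != number of samples")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  x1 <- expr[, groups == levels(groups)[1], drop = FALSE]
  x2 <- expr[, groups == levels(groups)[2], drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  logFC <- m2 - m1
  df <- n1 + n2 - 2
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / df

  if (is.null(df_prior) || is.null(s2_prior)) {
    prior <- fit_variance_prior(s2, df)
    if (is.null(df_prior)) df_prior <- prior$df_prior
    if (is.null(s2_prior)) s2_prior <- prior$s2_prior
  }
  s2_post <- if (is.infinite(df_prior)) rep(s2_prior, length(s2))
             else (df_prior * s2_prior + df * s2) / (df_prior + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- logFC / se
  df_total <- if (is.infinite(df_prior)) Inf else df_prior + df
  p <- 2 * pt(-abs(t_mod), df = df_total)
  res <- data.frame(
    feature_id = rownames(expr) %||% as.character(seq_along(logFC)),
    logFC = logFC, t_mod = t_mod, p = p, fdr = bh_adjust(p),
    s2 = s2, s2_post = s2_post,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res[[paste0("mean_", levels(groups)[1])]] <- unname(m1)
  res[[paste0("mean_", levels(groups)[2])]] <- unname(m2)
  attr(res, "df_prior") <- df_prior
  attr(res, "s2_prior") <- s2_prior
  attr(res, "df_residual") <- df
  res
}

#' Threshold differential-expression results
#'
#' Keep features with FDR-adjusted p at most `max_p` and absolute log2
#' fold change at least `min_abs_logFC`.
#'
#' @param results output of [moderated_t_de()].
#' @param max_p maximum adjusted p-value.
#' @param min_abs_logFC minimum |logFC|.
#' @return subset of `results`.
#' @export
filter_de <- function(results, max_p = 0.05, min_abs_logFC = 1) {
  stopifnot(!is.na(max_p), !is.na(min_abs_logFC))
  results[results$fdr <= max_p & abs(results$logFC) >= min_abs_logFC, ,
          drop = FALSE]
}

#' Correlation screen between expression features and covariates
#'
#' Computes Pearson or Spearman correlation for every (feature,
#' covariate) pair over the samples shared by name between the two
#' matrices, using pairwise-complete observations, and reports only
#' pairs with |r| strictly greater than `min_abs_r` (default 0.5).
#' Spearman uses average ranks for ties. Two-sided p-values come from
#' the t-transform t = r sqrt((n-2)/(1-r^2)) on n-2 df. Pairs with a
#' zero-variance vector (r undefined) or fewer than 3 complete pairs are
#' skipped and listed in the `skipped` attribute.
#'
#' @param expr numeric matrix (features x samples) or `NormalizedMatrix`.
#' @param covariates numeric matrix (covariates x samples) with sample
#'   names on columns.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_abs_r strict reporting threshold on |r| (default 0.5).
#' @return data.frame with `feature_id`, `covariate_id`, `method`, `r`,
#'   `n`, `p`, one row per reported pair; attribute `skipped` lists
#'   undefined pairs with reasons.
#' @export
correlate <- function(expr, covariates, method = c("pearson", "spearman"),
                      min_abs_r = 0.5) {
  method <- match.arg(method)
  if (is(expr, "NormalizedMatrix")) expr <- expr$values
  shared <- intersect(colnames(expr), colnames(covariates))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  e <- expr[, shared, drop = FALSE]
  cv <- covariates[, shared, drop = FALSE]
  r <- suppressWarnings(
    stats::cor(t(e), t(cv), method = method, use = "pairwise.complete.obs"))
  n <- crossprod(t(!is.na(e)) * 1, t(!is.na(cv)) * 1)
  idx <- which(!is.na(r) & n >= 3, arr.ind = TRUE)
  skipped_idx <- which(is.na(r) | n < 3, arr.ind = TRUE)
  skipped <- data.frame(
    feature_id = rownames(e)[skipped_idx[, 1]],
    covariate_id = rownames(cv)[skipped_idx[, 2]],
    reason = ifelse(n[skipped_idx] < 3, "fewer than 3 complete pairs",
                    "zero-variance vector (r undefined)"),
    stringsAsFactors = FALSE
  )
  rv <- r[idx]; nv <- n[idx]
  tv <- rv * sqrt((nv - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pv <- 2 * pt(-abs(tv), df = nv - 2)
  out <- data.frame(
    feature_id = rownames(e)[idx[, 1]],
    covariate_id = rownames(cv)[idx[, 2]],
    method = method, r = rv, n = as.integer(nv), p = pv,
    stringsAsFactors = FALSE
  )
  out <- out[abs(out$r) > min_abs_r, , drop = FALSE]
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
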