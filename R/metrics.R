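#' Redundancy gain of bimodal over best-unimodal performance
#'
#' The relative reduction of response dispersion brought by the redundant
#' bimodal stimulus:
#' \deqn{RG = 100 (ve_{uni} - ve_{bi}) / ve_{uni}}
#' with `ve` the variable error (deg) of the best unimodal condition
#' (conventionally vision) and of the bimodal condition; positive values
#' indicate multisensory improvement. The raw variance ratio
#' `100 * ve_bi^2 / ve_uni^2` is available as `method = "printed_ratio"`,
#' but note it measures *residual* variance, not gain, and is inconsistent
#' with gain-style readings of its values.
#'
#' @param ve_best_unimodal,ve_bimodal Variable errors in degrees
#'   (`ve_best_unimodal > 0`). Vectorized.
#' @param method `"reduction"` (default) or `"printed_ratio"`.
#' @return Gain(s) in percent.
#' @examples
#' redundancy_gain(1.78, 1.46)  # about 18
#' @export
redundancy_gain <- function(ve_best_unimodal, ve_bimodal,
                            method = c("reduction", "printed_ratio")) {
  method <- match.arg(method)
  if (any(ve_best_unimodal <= 0)) stop("unimodal VE must be > 0")
  switch(method,
         reduction = 100 * (ve_best_unimodal - ve_bimodal) / ve_best_unimodal,
         printed_ratio = 100 * ve_bimodal^2 / ve_best_unimodal^2)
}

#' Inverse effectiveness: correlation of redundancy gain with unimodal
#' reliability
#'
#' Under inverse effectiveness the multisensory gain grows as the best
#' unimodal estimate becomes less reliable, i.e. RG correlates positively
#' with the best-unimodal dispersion (or variance) across targets.
#'
#' @param rg_per_target Redundancy gains (percent).
#' @param ve_best_per_target Best-unimodal variable errors (deg).
#' @param square Correlate against the variance (`ve^2`) instead of the
#'   dispersion.
#' @return List with `estimate`, `p_value`, `n`, and `undefined` (TRUE when
#'   either input has zero variance, in which case the correlation does not
#'   exist and no value is propagated).
#' @export
inverse_effectiveness <- function(rg_per_target, ve_best_per_target,
                                  square = FALSE) {
  stopifnot(length(rg_per_target) == length(ve_best_per_target))
  if (length(rg_per_target) < 3) stop("at least 3 targets are required")
  x <- if (square) ve_best_per_target^2 else ve_best_per_target
  if (stats::sd(rg_per_target) == 0 || stats::sd(x) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_,
                n = length(x), undefined = TRUE))
  ct <- stats::cor.test(rg_per_target, x)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), undefined = FALSE)
}

#' Hierarchical (sequential) linear regression with collinearity diagnostics
#'
#' Fits nested least-squares models adding predictors in the given order and
#' reports, per step, R^2, adjusted R^2, the R^2 change and its F test, plus
#' the variance inflation factor of each predictor in the full model
#' (VIF = 1 for orthogonal predictors).
#'
#' @param response Numeric response vector.
#' @param predictors Data frame of predictors, columns in entry order.
#' @return Object of class `"hier_reg"`: `steps` (data frame: step,
#'   predictors, r2, adj_r2, r2_change, f_change, p_change, rank_deficient)
#'   and `vif` (named vector).
#' @export
hierarchical_regression <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  n <- length(response)
  p <- ncol(predictors)
  if (n <= p + 1) stop("need more observations than predictors + 1")
  steps <- vector("list", p)
  prev_r2 <- 0; prev_df <- n - 1
  tss <- sum((response - mean(response))^2)
  for (k in seq_len(p)) {
    X <- cbind(`(Constant)` = 1, as.matrix(predictors[, seq_len(k), drop = FALSE]))
    fit <- stats::lm.fit(X, response)
    deficient <- fit$rank < ncol(X)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    df_res <- n - fit$rank
    adj <- 1 - (1 - r2) * (n - 1) / df_res
    dr2 <- r2 - prev_r2
    df_change <- prev_df - df_res
    f <- if (df_change > 0 && rss > 0)
      (dr2 / df_change) / ((1 - r2) / df_res) else NA_real_
    pval <- if (is.na(f)) NA_real_ else stats::pf(f, df_change, df_res,
                                                  lower.tail = FALSE)
    steps[[k]] <- data.frame(step = k,
                             predictors = paste(names(predictors)[seq_len(k)],
                                                collapse = " + "),
                             r2 = r2, adj_r2 = adj, r2_change = dr2,
                             f_change = f, p_change = pval,
                             rank_deficient = deficient)
    prev_r2 <- r2; prev_df <- df_res
  }
  vif <- vapply(seq_len(p), function(j) {
    if (p == 1) return(1)
    others <- as.matrix(predictors[, -j, drop = FALSE])
    fit <- stats::lm.fit(cbind(1, others), predictors[[j]])
    r2j <- 1 - sum(fit$residuals^2) /
      sum((predictors[[j]] - mean(predictors[[j]]))^2)
    1 / (1 - min(r2j, 1 - 1e-12))
  }, numeric(1))
  names(vif) <- names(predictors)
  structure(list(steps = do.call(rbind, steps), vif = vif),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, digits = 3, ...) {
  cat("Hierarchical regression (method: sequential entry)\n")
  print(format(x$steps, digits = digits), row.names = FALSE)
  cat("VIF:", paste(sprintf("%s = %.2f", names(x$vif), x$vif),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Paired comparison of an observed and a predicted per-target field
#'
#' @param observed,predicted Named numeric vectors of a per-target metric
#'   (e.g. VE) on matched target sets (>= 3 targets); names, when present,
#'   must agree and are used for alignment.
#' @return List with `mean_difference` (observed - predicted), `t`,
#'   `p_value`, `df`, `correlation`, `n`, `degenerate` (TRUE when the paired
#'   differences have zero variance; then `p_value` is 1 for identical-mean
#'   fields rather than NaN).
#' @export
compare_fields <- function(observed, predicted) {
  if (!is.null(names(observed)) && !is.null(names(predicted))) {
    if (!setequal(names(observed), names(predicted)))
      stop("observed and predicted target sets do not match")
    predicted <- predicted[names(observed)]
  } else if (length(observed) != length(predicted))
    stop("observed and predicted fields have different lengths")
  n <- length(observed)
  if (n < 3) stop("at least 3 targets are required")
  d <- observed - predicted
  corr <- if (stats::sd(observed) > 0 && stats::sd(predicted) > 0)
    stats::cor(observed, predicted) else NA_real_
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # constant difference field: the paired t statistic does not exist
    return(list(mean_difference = mean(d), t = NA_real_,
                p_value = if (abs(mean(d)) <= 1e-10) 1 else NA_real_,
                df = n - 1, correlation = corr, n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(observed, predicted, paired = TRUE)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       p_value = tt$p.value, df = unname(tt$parameter),
       correlation = corr, n = n, degenerate = FALSE)
}
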