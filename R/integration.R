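#' Multisensory integration metrics for a fitted localization field
#'
#' Quantifies how the bimodal condition improves on the best unimodal one
#' and how well the maximum-likelihood prediction accounts for it:
#'
#' * per-target and mean redundancy gain (observed VA vs best unimodal, and
#'   predicted MLE vs best unimodal);
#' * inverse effectiveness: correlation of the observed gain with the
#'   best-unimodal dispersion across targets (positive = more gain where the
#'   best single cue is least reliable);
#' * per-axis visual weights from the prediction and their relation to
#'   bimodal accuracy (weight-accuracy correlation);
#' * hierarchical regressions of the bimodal 2D variance on the visual then
#'   auditory 2D variances (observed and predicted responses), with VIFs;
#' * a paired observed-vs-predicted precision comparison
#'   ([compare_fields()]).
#'
#' Precision enters through the pooled per-target VE (see [locfield()] for
#' the two conventions).
#'
#' @param object A [locfield()] fit with `A`, `V` and `VA` conditions.
#' @param prediction A [predict.locfield()] result; computed if missing.
#' @param best `"V"` (convention: vision is the more effective unisensory
#'   condition) or `"argmin"` (per-target best unimodal VE).
#' @return Object of class `"integration_report"`; see Details.
#' @export
integration_report <- function(object, prediction = predict(object),
                               best = c("V", "argmin")) {
  best <- match.arg(best)
  pt <- object$per_target[object$per_target$retained, ]
  pp <- prediction$per_target[prediction$per_target$retained, ]
  need <- c("A", "V", "VA")
  if (!all(need %in% pt$modality))
    stop("integration metrics require A, V and VA conditions")
  wide <- function(col, d = pt) {
    out <- lapply(split(d, d$modality), function(z)
      stats::setNames(z[[col]], z$target_id))
    out
  }
  ids <- as.character(sort(unique(pt$target_id[pt$modality == "VA"])))
  ve <- wide("ve_pooled"); vt <- wide("var_total"); ce <- wide("ce_pooled")
  ve_mle <- stats::setNames(pp$ve_pooled, pp$target_id)[ids]
  ve_va <- ve$VA[ids]; ve_v <- ve$V[ids]; ve_a <- ve$A[ids]
  ve_best <- if (best == "V") ve_v else pmin(ve_v, ve_a)
  rg_obs <- redundancy_gain(ve_best, ve_va)
  rg_pred <- redundancy_gain(ve_best, ve_mle)
  ie <- inverse_effectiveness(rg_obs, ve_best)
  ie_pred <- inverse_effectiveness(rg_pred, ve_best)
  w_v_x <- stats::setNames(pp$w_v_x, pp$target_id)[ids]
  w_v_y <- stats::setNames(pp$w_v_y, pp$target_id)[ids]
  w_v <- (w_v_x + w_v_y) / 2
  ce_va <- ce$VA[ids]
  wac <- if (stats::sd(w_v) > 0 && stats::sd(ce_va) > 0) {
    ct <- stats::cor.test(w_v, ce_va)
    list(estimate = unname(ct$estimate), p_value = ct$p.value)
  } else list(estimate = NA_real_, p_value = NA_real_)
  reg_obs <- hierarchical_regression(vt$VA[ids],
                                     data.frame(var_v = vt$V[ids],
                                                var_a = vt$A[ids]))
  reg_pred <- hierarchical_regression(
    stats::setNames(pp$var_total, pp$target_id)[ids],
    data.frame(var_v = vt$V[ids], var_a = vt$A[ids]))
  cmp <- compare_fields(ve_va, ve_mle)
  structure(list(targets = ids,
                 rg_per_target = rg_obs, rg_mean = mean(rg_obs),
                 rg_pred_per_target = rg_pred, rg_pred_mean = mean(rg_pred),
                 ie_correlation = ie, ie_correlation_pred = ie_pred,
                 w_v_x = w_v_x, w_v_y = w_v_y,
                 w_v_x_mean = mean(w_v_x), w_v_y_mean = mean(w_v_y),
                 weight_accuracy_correlation = wac,
                 regression_observed = reg_obs,
                 regression_predicted = reg_pred,
                 observed_vs_predicted = cmp,
                 best = best),
            class = "integration_report")
}

#' @export
print.integration_report <- function(x, digits = 3, ...) {
  cat("Multisensory integration report\n")
  cat(sprintf("  redundancy gain: observed %.2f%%, predicted %.2f%% (best unimodal: %s)\n",
              x$rg_mean, x$rg_pred_mean, x$best))
  cat(sprintf("  inverse effectiveness (RG vs best VE): r = %.3f (p = %.3g); model: r = %.3f (p = %.3g)\n",
              x$ie_correlation$estimate, x$ie_correlation$p_value,
              x$ie_correlation_pred$estimate, x$ie_correlation_pred$p_value))
  cat(sprintf("  visual weight: azimuth %.3f, elevation %.3f (range %.2f-%.2f)\n",
              x$w_v_x_mean, x$w_v_y_mean,
              min(c(x$w_v_x, x$w_v_y)), max(c(x$w_v_x, x$w_v_y))))
  cat(sprintf("  weight-accuracy correlation (W_V vs CE_VA): r = %.3f (p = %.3g)\n",
              x$weight_accuracy_correlation$estimate,
              x$weight_accuracy_correlation$p_value))
  cat(sprintf("  observed vs predicted precision: mean diff %.4f deg, t = %.2f, p = %.3g\n",
              x$observed_vs_predicted$mean_difference,
              x$observed_vs_predicted$t, x$observed_vs_predicted$p_value))
  cat("  observed VA variance regression:\n")
  print(format(x$regression_observed$steps[, c("predictors", "r2", "adj_r2",
                                               "r2_change", "p_change")],
               digits = digits), row.names = FALSE)
  invisible(x)
}
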