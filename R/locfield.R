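#' Fit per-target localization fields from trial-level pointing data
#'
#' The central estimator: for every modality x target cell it screens
#' outliers per subject ([filter_outliers()]), estimates the bivariate
#' response distribution ([estimate_distribution()]), and derives the
#' precision geometry (95% confidence ellipse, orientation, anisotropy) and
#' the accuracy field (constant-error vectors, their direction deviations,
#' and the global affine target-to-endpoint map per modality).
#'
#' Two summary conventions coexist and are both computed: scalar precision
#' and accuracy measures (VE, CE) are reported per subject and then averaged
#' (`ve`, `ce`), matching the per-subject screening pipeline, and also from
#' the distribution pooled over subjects (`ve_pooled`, `ce_pooled`), which
#' has smaller small-sample bias; ellipse geometry is always computed from
#' the pooled distribution. Targets beyond `max_abs_az` in azimuth are kept
#' in the table but flagged `retained = FALSE` and excluded from summaries,
#' affine fits and integration metrics, so that azimuth and elevation
#' extents compare like for like.
#'
#' @param data A `"response_data"` data frame ([simulate_responses()],
#'   [read_responses()]).
#' @param grid The target grid; defaults to the one attached to `data`.
#' @param outlier_k SD multiplier of the outlier screen (default 3).
#' @param coverage Confidence-ellipse coverage (default 0.95).
#' @param max_abs_az Retention bound on |azimuth| (default 20).
#' @return An object of class `"locfield"` with components `per_target`
#'   (data frame: modality, target_id, az/el, n, moments, VE/CE in both
#'   conventions, ellipse geometry, error-vector measures, `retained`),
#'   `summaries` (nested list of pooled [dist_summary] objects by modality
#'   then target id), `subject_summaries` (same, by subject), `affine`
#'   (per-modality [fit_affine()] over retained targets), `removal`
#'   (the outlier report), `grid`, `coverage`, `call`.
#' @seealso [predict.locfield()] for the MLE-predicted bimodal field,
#'   [integration_report()] for multisensory integration metrics,
#'   [run_pipeline()] for the end-to-end driver.
#' @export
locfield <- function(data, grid = attr(data, "grid"), outlier_k = 3,
                     coverage = 0.95, max_abs_az = 20) {
  if (is.null(grid)) stop("data has no attached target grid")
  flt <- filter_outliers(data, k = outlier_k)
  dat <- flt$data
  modalities <- intersect(c("A", "V", "VA"), unique(dat$modality))
  subjects <- sort(unique(dat$subject))

  summaries <- list(); subject_summaries <- list()
  rows <- list(); r <- 0L
  for (m in modalities) {
    dm <- dat[dat$modality == m, , drop = FALSE]
    summaries[[m]] <- list()
    subject_summaries[[m]] <- list()
    for (i in seq_len(nrow(grid))) {
      tid <- grid$target_id[i]
      az <- grid$az_deg[i]; el <- grid$el_deg[i]
      dmt <- dm[dm$target_id == tid, , drop = FALSE]
      if (nrow(dmt) < 2) next
      pooled <- estimate_distribution(dmt$x_deg, dmt$y_deg)
      summaries[[m]][[as.character(tid)]] <- pooled
      per_subj <- lapply(split(dmt, dmt$subject, drop = TRUE), function(d)
        if (nrow(d) >= 2) estimate_distribution(d$x_deg, d$y_deg) else NULL)
      per_subj <- per_subj[!vapply(per_subj, is.null, TRUE)]
      subject_summaries[[m]][[as.character(tid)]] <- per_subj
      ve_s <- vapply(per_subj, function(s) sqrt(s$var_total), numeric(1))
      ce_s <- vapply(per_subj, function(s)
        error_vector(s, az, el)$r, numeric(1))
      ell <- confidence_ellipse(pooled, coverage)
      ev <- error_vector(pooled, az, el)
      tdir <- target_direction(az, el)
      r <- r + 1L
      rows[[r]] <- data.frame(
        modality = m, target_id = tid, az_deg = az, el_deg = el,
        n = pooled$n, n_subjects = length(per_subj),
        mu_x = pooled$mu_x, mu_y = pooled$mu_y,
        var_x = pooled$var_x, var_y = pooled$var_y, rho = pooled$rho,
        var_total = pooled$var_total,
        ve = if (length(ve_s)) mean(ve_s) else sqrt(pooled$var_total),
        ve_pooled = sqrt(pooled$var_total),
        ce = if (length(ce_s)) mean(ce_s) else ev$r,
        ce_pooled = ev$r,
        a = ell$a, b = ell$b, theta_deg = ell$theta_deg,
        epsilon = ell$epsilon,
        orientation_undefined = ell$orientation_undefined,
        orientation_dev = if (is.na(tdir)) NA_real_ else
          axial_deviation(ell$theta_deg, tdir),
        r_err = ev$r, alpha_deg = if (is.null(ev$alpha_deg)) NA_real_ else ev$alpha_deg,
        circular_dev = ev$circular_dev, axial_dev = ev$axial_dev,
        retained = abs(az) <= max_abs_az)
    }
  }
  per_target <- do.call(rbind, rows)
  rownames(per_target) <- NULL

  affine <- list()
  for (m in modalities) {
    pt <- per_target[per_target$modality == m & per_target$retained, ]
    if (nrow(pt) >= 3)
      affine[[m]] <- fit_affine(cbind(pt$az_deg, pt$el_deg),
                                cbind(pt$mu_x, pt$mu_y))
  }
  structure(list(per_target = per_target, summaries = summaries,
                 subject_summaries = subject_summaries, affine = affine,
                 removal = flt$report, data = dat, grid = grid,
                 coverage = coverage, outlier_k = outlier_k,
                 max_abs_az = max_abs_az, call = match.call()),
            class = "locfield")
}

#' @export
print.locfield <- function(x, ...) {
  pt <- x$per_target
  mods <- unique(pt$modality)
  cat("Localization field fit\n")
  cat(sprintf("  %d modalities (%s), %d targets (%d retained), %d subjects\n",
              length(mods), paste(mods, collapse = ", "),
              length(unique(pt$target_id)),
              length(unique(pt$target_id[pt$retained])),
              max(pt$n_subjects, na.rm = TRUE)))
  for (m in mods) {
    d <- pt[pt$modality == m & pt$retained, ]
    cat(sprintf("  %-3s mean VE %5.2f deg, mean CE %5.2f deg\n",
                m, mean(d$ve), mean(d$ce)))
  }
  cat(sprintf("  outlier screen removed %.2f%% of trials\n",
              100 * sum(x$removal$by_modality$n_removed) /
                sum(x$removal$by_modality$n_before)))
  invisible(x)
}

#' @export
summary.locfield <- function(object, stat = c("by_subject", "pooled"),
                             prediction = NULL, ...) {
  stat <- match.arg(stat)
  pt <- object$per_target[object$per_target$retained, ]
  if (!is.null(prediction)) {
    pp <- prediction$per_target[prediction$per_target$retained, ]
    pt <- rbind(pt, pp[names(pt)])
  }
  ve_col <- if (stat == "by_subject") "ve" else "ve_pooled"
  ce_col <- if (stat == "by_subject") "ce" else "ce_pooled"
  mods <- intersect(c("A", "V", "VA", "MLE"), unique(pt$modality))
  tab <- sapply(mods, function(m) {
    d <- pt[pt$modality == m, ]
    c(ve_mean = mean(d[[ve_col]]), ve_sd = stats::sd(d[[ve_col]]),
      ce_mean = mean(d[[ce_col]]), ce_sd = stats::sd(d[[ce_col]]),
      orientation_dev_mean = mean(d$orientation_dev, na.rm = TRUE),
      orientation_dev_sd = stats::sd(d$orientation_dev, na.rm = TRUE),
      direction_dev_mean = mean(d$axial_dev, na.rm = TRUE),
      direction_dev_sd = stats::sd(d$axial_dev, na.rm = TRUE))
  })
  structure(list(table = tab, stat = stat,
                 n_targets = length(unique(pt$target_id)),
                 removal = object$removal),
            class = "summary.locfield")
}

#' @export
print.summary.locfield <- function(x, digits = 2, ...) {
  cat(sprintf("Localization performance over %d retained targets (%s statistics)\n",
              x$n_targets,
              if (x$stat == "by_subject") "per-subject-then-mean" else "pooled"))
  tab <- x$table
  measures <- c("Variable error (deg)" = "ve",
                "Constant error (deg)" = "ce",
                "Orientation deviation (deg)" = "orientation_dev",
                "Direction deviation (deg)" = "direction_dev")
  header <- paste0(formatC("", width = 28),
                   paste(formatC(colnames(tab), width = 14), collapse = ""))
  cat(header, "\n")
  for (i in seq_along(measures)) {
    vals <- sprintf("%6.2f (%.2f)",
                    tab[paste0(measures[i], "_mean"), ],
                    tab[paste0(measures[i], "_sd"), ])
    cat(formatC(names(measures)[i], width = 28, flag = "-"),
        paste(formatC(vals, width = 14), collapse = ""), "\n")
  }
  invisible(x)
}

#' Predict the bimodal field from fitted unimodal fields (the MLE condition)
#'
#' Fuses the fitted visual and auditory distributions target by target with
#' [fuse_gaussians_2d()] and derives the same geometry as for an observed
#' condition. With `pooling = "pooled"` (default) the subject-pooled
#' per-target distributions are fused; with `"by_subject"` fusion is done
#' within each subject and parameters are then averaged across subjects
#' (the per-subject route carries a noticeable small-sample bias: the
#' harmonic variance combination is concave in the sample variances, so with
#' few trials per cell the predicted variance runs low).
#'
#' @param object A [locfield()] fit containing both `A` and `V` conditions.
#' @param pooling `"pooled"` or `"by_subject"`.
#' @param ... Unused.
#' @return Object of class `"locfield_pred"`: `per_target` (same layout as
#'   the fit's table, modality `"MLE"`), `fusions` (named list of
#'   `"fusion_result"`), `pooling`.
#' @export
predict.locfield <- function(object, pooling = c("pooled", "by_subject"), ...) {
  pooling <- match.arg(pooling)
  sv <- object$summaries$V; sa <- object$summaries$A
  if (is.null(sv) || is.null(sa))
    stop("prediction requires both V and A conditions in the fit")
  ids <- intersect(names(sv), names(sa))
  if (!length(ids)) stop("no common targets between V and A fits")
  fus <- predict_bimodal_field(sv[ids], sa[ids])
  if (pooling == "by_subject") {
    ssv <- object$subject_summaries$V; ssa <- object$subject_summaries$A
    for (k in ids) {
      subs <- intersect(names(ssv[[k]]), names(ssa[[k]]))
      if (length(subs) < 1) next
      fs <- lapply(subs, function(s) fuse_gaussians_2d(ssv[[k]][[s]],
                                                       ssa[[k]][[s]]))
      mu <- rowMeans(vapply(fs, `[[`, numeric(2), "mu"))
      sigma <- Reduce(`+`, lapply(fs, `[[`, "sigma")) / length(fs)
      f <- fus[[k]]
      f$mu <- mu; f$sigma <- sigma
      f$var_x <- sigma[1, 1]; f$var_y <- sigma[2, 2]
      f$var_total <- sum(diag(sigma))
      f$w_v_x <- mean(vapply(fs, `[[`, numeric(1), "w_v_x"))
      f$w_v_y <- mean(vapply(fs, `[[`, numeric(1), "w_v_y"))
      f$w_a_x <- 1 - f$w_v_x; f$w_a_y <- 1 - f$w_v_y
      f$ve_subject_mean <- mean(vapply(fs, function(z) sqrt(z$var_total),
                                       numeric(1)))
      fus[[k]] <- f
    }
  }
  rows <- lapply(ids, function(k) {
    g <- grid_lookup(object$grid, as.integer(k))
    f <- fus[[k]]
    ds <- as_dist_summary(f)
    ell <- confidence_ellipse(ds, object$coverage)
    ev <- error_vector(ds, g$az_deg, g$el_deg)
    tdir <- target_direction(g$az_deg, g$el_deg)
    data.frame(modality = "MLE", target_id = g$target_id,
               az_deg = g$az_deg, el_deg = g$el_deg,
               n = NA_integer_, n_subjects = NA_integer_,
               mu_x = f$mu[1], mu_y = f$mu[2],
               var_x = f$var_x, var_y = f$var_y, rho = ds$rho,
               var_total = f$var_total,
               ve = if (!is.null(f$ve_subject_mean)) f$ve_subject_mean
                    else sqrt(f$var_total),
               ve_pooled = sqrt(f$var_total),
               ce = ev$r, ce_pooled = ev$r,
               a = ell$a, b = ell$b, theta_deg = ell$theta_deg,
               epsilon = ell$epsilon,
               orientation_undefined = ell$orientation_undefined,
               orientation_dev = if (is.na(tdir)) NA_real_ else
                 axial_deviation(ell$theta_deg, tdir),
               r_err = ev$r, alpha_deg = ev$alpha_deg,
               circular_dev = ev$circular_dev, axial_dev = ev$axial_dev,
               w_v_x = f$w_v_x, w_v_y = f$w_v_y,
               retained = abs(g$az_deg) <= object$max_abs_az)
  })
  per_target <- do.call(rbind, rows)
  rownames(per_target) <- NULL
  structure(list(per_target = per_target, fusions = fus, pooling = pooling),
            class = "locfield_pred")
}

#' @export
print.locfield_pred <- function(x, ...) {
  pt <- x$per_target[x$per_target$retained, ]
  cat(sprintf("MLE-predicted bimodal field (%s fusion), %d targets\n",
              x$pooling, nrow(pt)))
  cat(sprintf("  mean VE %.3f deg, mean CE %.3f deg, mean W_V (x %.3f, y %.3f)\n",
              mean(pt$ve), mean(pt$ce), mean(pt$w_v_x), mean(pt$w_v_y)))
  invisible(x)
}

#' @export
coef.locfield <- function(object, ...) {
  t(vapply(object$affine, function(a)
    c(scale_x = a$scale_x, scale_y = a$scale_y,
      rotation_deg = a$rotation_deg, shear = a$shear,
      tx = a$translation[1], ty = a$translation[2],
      rms_residual = a$rms_residual), numeric(7)))
}

#' @export
residuals.locfield <- function(object, ...) {
  pt <- object$per_target
  data.frame(modality = pt$modality, target_id = pt$target_id,
             dx = pt$mu_x - pt$az_deg, dy = pt$mu_y - pt$el_deg,
             r = pt$r_err, alpha_deg = pt$alpha_deg,
             circular_dev = pt$circular_dev, axial_dev = pt$axial_dev,
             retained = pt$retained)
}

#' Simulate new datasets from a fitted localization field
#'
#' Parametric-bootstrap draws: each simulated dataset redraws every
#' modality x target cell from the fitted pooled bivariate normal, with the
#' observed number of responses per cell.
#'
#' @param object A [locfield()] fit.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `"response_data"` data frames (length `nsim`).
#' @export
simulate.locfield <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pt <- object$per_target
  counts <- table(object$data$subject,
                  paste(object$data$modality, object$data$target_id))
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    recs <- list(); i <- 0L
    for (j in seq_len(nrow(pt))) {
      m <- pt$modality[j]; tid <- pt$target_id[j]
      ds <- object$summaries[[m]][[as.character(tid)]]
      L <- t(chol(cov_matrix(ds)))
      key <- paste(m, tid)
      for (s in rownames(counts)) {
        n <- counts[s, key]
        if (n == 0) next
        z <- matrix(stats::rnorm(2 * n), 2, n)
        xy <- c(ds$mu_x, ds$mu_y) + L %*% z
        i <- i + 1L
        recs[[i]] <- data.frame(subject = s, modality = m, target_id = tid,
                                rep = seq_len(n) - 1L,
                                x_deg = xy[1, ], y_deg = xy[2, ])
      }
    }
    d <- do.call(rbind, recs)
    rownames(d) <- NULL
    attr(d, "grid") <- object$grid
    class(d) <- c("response_data", "data.frame")
    out[[k]] <- d
  }
  out
}
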