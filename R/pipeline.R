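#' Run the full localization-analysis pipeline
#'
#' End-to-end driver: obtain trial-level data (either read from `input` or
#' simulated from `profiles`), screen outliers, fit the per-target fields
#' ([locfield()]), predict the bimodal field by maximum-likelihood fusion
#' ([predict.locfield()]), compute integration metrics
#' ([integration_report()]) and write the artifact bundle to `out_dir`:
#'
#' * `per_target.csv` — per-target summary table for A, V, VA and the
#'   predicted MLE condition (moments, VE/CE, ellipse geometry, error
#'   vectors, weights);
#' * `summary_table.csv` — the condition x measure summary (mean and SD of
#'   VE, CE, orientation deviation, direction deviation);
#' * `integration.csv` / `integration.txt` — per-target gains and weights,
#'   and the full printed report;
#' * `removal.csv` — outlier screen accounting (every excluded record is
#'   attributable to a cell);
#' * `affine.csv` — per-modality affine map parameters;
#' * `distortion_edges.csv` — centroid lattice edges for distortion plots;
#' * `run_log.txt` — seed, package and R versions, options in effect;
#' * optional `plots.pdf` with ellipse/vector/distortion maps per condition.
#'
#' The pipeline is a pure function of (input data, options, seed): rerunning
#' with the same arguments reproduces every output byte for byte.
#'
#' @param input Optional path to a response CSV ([read_responses()]);
#'   exactly one of `input` / `simulate` must be active.
#' @param simulate Logical: generate data with [simulate_responses()]
#'   (default when `input` is missing).
#' @param profiles,n_subjects,n_reps,bimodal_mode Generator settings.
#' @param seed Integer seed for the generator.
#' @param grid Target grid for simulation.
#' @param outlier_k,coverage,max_abs_az Fit settings (see [locfield()]).
#' @param pooling Fusion pooling for the prediction.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing and just returns the objects.
#' @param plots Also write `plots.pdf` (default FALSE).
#' @return Invisibly, a list with `fit`, `prediction`, `integration`,
#'   `summary`, `data` and `files` (paths written).
#' @export
run_pipeline <- function(input = NULL, simulate = is.null(input),
                         profiles = default_profiles(),
                         n_subjects = 10L, n_reps = 10L,
                         bimodal_mode = "mle_exact",
                         seed = 1L, grid = target_grid(),
                         outlier_k = 3, coverage = 0.95, max_abs_az = 20,
                         pooling = "pooled",
                         out_dir = NULL, plots = FALSE) {
  if (!is.null(input) && simulate)
    stop("give either an input path or simulate = TRUE, not both")
  dat <- if (!is.null(input)) read_responses(input)
         else simulate_responses(grid = grid, profiles = profiles,
                                 n_subjects = n_subjects, n_reps = n_reps,
                                 bimodal_mode = bimodal_mode, seed = seed)
  fit <- locfield(dat, outlier_k = outlier_k, coverage = coverage,
                  max_abs_az = max_abs_az)
  pred <- predict(fit, pooling = pooling)
  integ <- if (all(c("A", "V", "VA") %in% unique(dat$modality)))
    integration_report(fit, pred) else NULL
  summ <- summary(fit, prediction = pred)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(d, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(d, path, row.names = FALSE)
      files <<- c(files, path)
    }
    cols <- intersect(names(fit$per_target), names(pred$per_target))
    wcsv(rbind(fit$per_target[cols], pred$per_target[cols]), "per_target.csv")
    tab <- as.data.frame(t(summ$table))
    tab <- cbind(condition = rownames(tab), tab)
    wcsv(tab, "summary_table.csv")
    if (!is.null(integ)) {
      wcsv(data.frame(target_id = integ$targets,
                      rg_observed = integ$rg_per_target,
                      rg_predicted = integ$rg_pred_per_target,
                      w_v_x = integ$w_v_x, w_v_y = integ$w_v_y),
           "integration.csv")
      txt <- file.path(out_dir, "integration.txt")
      writeLines(utils::capture.output(print(integ)), txt)
      files <- c(files, txt)
    }
    wcsv(fit$removal$cells, "removal.csv")
    co <- coef(fit)
    wcsv(cbind(modality = rownames(co), as.data.frame(co)), "affine.csv")
    edges <- do.call(rbind, lapply(names(fit$affine), function(m) {
      pt <- fit$per_target[fit$per_target$modality == m &
                             fit$per_target$retained, ]
      g <- fit$grid[fit$grid$target_id %in% pt$target_id, , drop = FALSE]
      class(g) <- class(fit$grid)
      attr(g, "spacing_deg") <- attr(fit$grid, "spacing_deg")
      dg <- distortion_grid(data.frame(target_id = pt$target_id,
                                       x = pt$mu_x, y = pt$mu_y), g)
      if (nrow(dg$edges)) cbind(modality = m, dg$edges) else NULL
    }))
    if (!is.null(edges)) wcsv(edges, "distortion_edges.csv")
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      "locfuse pipeline run",
      paste("seed:", seed),
      paste("R version:", R.version.string),
      paste("package version:",
            as.character(utils::packageVersion("locfuse"))),
      paste("source:", if (!is.null(input)) input else
        sprintf("simulated (%d subjects x %d reps, bimodal_mode %s)",
                n_subjects, n_reps, bimodal_mode)),
      paste("outlier k:", outlier_k),
      paste("ellipse coverage:", coverage),
      paste("azimuth retention bound:", max_abs_az),
      paste("fusion pooling:", pooling)), log_path)
    files <- c(files, log_path)
    if (plots) {
      pdf_path <- file.path(out_dir, "plots.pdf")
      grDevices::pdf(pdf_path, width = 8, height = 6)
      for (m in unique(fit$per_target$modality))
        for (w in c("ellipses", "vectors", "distortion"))
          plot(fit, which = w, modality = m)
      grDevices::dev.off()
      files <- c(files, pdf_path)
    }
  }
  invisible(list(fit = fit, prediction = pred, integration = integ,
                 summary = summ, data = dat, files = files))
}
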