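#' Simulate trial-level localization responses
#'
#' Draws open-loop pointing endpoints for every subject x modality x target x
#' repetition cell. Each cell's clean responses are bivariate normal with the
#' closed-form mean and covariance given by [ground_truth_distribution()];
#' a small fraction of trials is replaced by gross outliers (uniform
#' direction, amplitude uniform on 4-8 local major-axis SDs).
#'
#' The bimodal condition is generated in one of two ways:
#' * `"mle_exact"` (default): the VA generating distribution at each target
#'   is the precision-weighted fusion ([fuse_gaussians_2d()]) of the A and V
#'   ground truths, i.e. the data embody exact maximum-likelihood
#'   integration; a `VA` profile, if present, contributes only its outlier
#'   parameters.
#' * `"independent_profile"`: the VA condition is drawn from its own
#'   [modality_profile()], which must then be present.
#'
#' Randomness is funnelled through per-subject seeds (`seed + 0:(n_subjects -
#' 1)` by default), so identical seeds give byte-identical datasets and
#' permuting `subject_seeds` permutes subjects.
#'
#' @param grid A [target_grid()].
#' @param profiles Named list of [modality_profile()]s covering `modalities`.
#' @param n_subjects,n_reps Numbers of subjects and of repetitions per cell
#'   (`n_reps >= 2`).
#' @param modalities Conditions to generate, subset of `c("A", "V", "VA")`.
#' @param bimodal_mode `"mle_exact"` or `"independent_profile"`.
#' @param seed Integer seed (optional); ignored if `subject_seeds` is given.
#' @param subject_seeds Optional integer vector of length `n_subjects`.
#' @return A data frame of class `"response_data"` with columns `subject`,
#'   `modality`, `target_id`, `rep` (0-based), `x_deg`, `y_deg`, and the grid
#'   attached as attribute `"grid"`.
#' @examples
#' dat <- simulate_responses(n_subjects = 2, n_reps = 3, seed = 1)
#' nrow(dat) # 2 * 3 modalities * 35 targets * 3 reps
#' @export
simulate_responses <- function(grid = target_grid(),
                               profiles = default_profiles(),
                               n_subjects = 10L,
                               n_reps = 10L,
                               modalities = c("A", "V", "VA"),
                               bimodal_mode = c("mle_exact", "independent_profile"),
                               seed = NULL,
                               subject_seeds = NULL) {
  bimodal_mode <- match.arg(bimodal_mode)
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  needed <- setdiff(modalities, "VA")
  if ("VA" %in% modalities && bimodal_mode == "independent_profile")
    needed <- c(needed, "VA")
  missing <- setdiff(needed, names(profiles))
  if (length(missing))
    stop("no profile for modality: ", paste(missing, collapse = ", "))
  if ("VA" %in% modalities && bimodal_mode == "mle_exact" &&
      !all(c("A", "V") %in% names(profiles)))
    stop("mle_exact bimodal generation needs both A and V profiles")
  if (is.null(subject_seeds) && !is.null(seed))
    subject_seeds <- as.integer(seed) + seq_len(n_subjects) - 1L
  if (!is.null(subject_seeds) && length(subject_seeds) != n_subjects)
    stop("subject_seeds must have length n_subjects")

  cells <- simulation_cells(grid, profiles, modalities, bimodal_mode)
  nt <- nrow(grid)
  per_subj <- length(modalities) * nt * n_reps
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    if (!is.null(subject_seeds)) set.seed(subject_seeds[s])
    xy <- matrix(NA_real_, 2L, per_subj)
    col0 <- 0L
    for (cell in cells) {
      z <- matrix(stats::rnorm(2L * n_reps), 2L, n_reps)
      pts <- cell$mu + cell$L %*% z
      if (cell$outlier_rate > 0) {
        bad <- which(stats::runif(n_reps) < cell$outlier_rate)
        if (length(bad)) {
          amp <- stats::runif(length(bad), cell$outlier_scale / 2,
                              cell$outlier_scale) * cell$major_sd
          phi <- stats::runif(length(bad), 0, 2 * pi)
          pts[, bad] <- cell$mu + rbind(amp * cos(phi), amp * sin(phi))
        }
      }
      xy[, col0 + seq_len(n_reps)] <- pts
      col0 <- col0 + n_reps
    }
    out[[s]] <- data.frame(
      subject = sprintf("S%02d", s),
      modality = rep(vapply(cells, `[[`, "", "modality"), each = n_reps),
      target_id = rep(vapply(cells, `[[`, 0L, "target_id"), each = n_reps),
      rep = rep.int(seq_len(n_reps) - 1L, length(cells)),
      x_deg = xy[1L, ], y_deg = xy[2L, ])
  }
  dat <- do.call(rbind, out)
  rownames(dat) <- NULL
  attr(dat, "grid") <- grid
  class(dat) <- c("response_data", "data.frame")
  dat
}

# precompute mean, cholesky factor and outlier parameters per modality x target
simulation_cells <- function(grid, profiles, modalities, bimodal_mode) {
  cells <- list()
  k <- 0L
  for (m in modalities) {
    for (i in seq_len(nrow(grid))) {
      az <- grid$az_deg[i]; el <- grid$el_deg[i]
      if (m == "VA" && bimodal_mode == "mle_exact") {
        gv <- ground_truth_distribution(profiles$V, az, el)
        ga <- ground_truth_distribution(profiles$A, az, el)
        fused <- fuse_gaussians_2d(gv, ga)
        mu <- fused$mu; S <- fused$sigma
        p_out <- if ("VA" %in% names(profiles)) profiles$VA else NULL
        rate <- if (is.null(p_out)) mean(c(profiles$A$outlier_rate,
                                           profiles$V$outlier_rate))
                else p_out$outlier_rate
        oscale <- if (is.null(p_out)) 8 else p_out$outlier_scale
        major <- sqrt(eigen(S, symmetric = TRUE, only.values = TRUE)$values[1])
      } else {
        g <- ground_truth_distribution(profiles[[m]], az, el)
        mu <- c(g$mu_x, g$mu_y); S <- cov_matrix(g)
        rate <- profiles[[m]]$outlier_rate
        oscale <- profiles[[m]]$outlier_scale
        major <- attr(g, "major_sd")
      }
      k <- k + 1L
      cells[[k]] <- list(modality = m, target_id = grid$target_id[i],
                         mu = mu, L = t(chol(S)),
                         outlier_rate = rate, outlier_scale = oscale,
                         major_sd = major)
    }
  }
  cells
}
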