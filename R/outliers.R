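#' Remove outlying responses per subject x modality x target cell
#'
#' Within every cell a response is discarded when it lies more than `k`
#' standard deviations from the cell mean on either axis; the screen is a
#' single pass, with means and SDs computed from the unfiltered cell (so the
#' rule matches the conventional "+/- k SD from the mean" phrasing rather
#' than an iterative or Mahalanobis criterion — on clean bivariate-normal
#' data the expected removal at k = 3 is about 2 * 2 * pnorm(-3) = 0.54%).
#' Cells with fewer than 3 responses are passed through untouched and
#' flagged.
#'
#' @param dataset A `"response_data"` data frame.
#' @param k SD multiplier, default 3.
#' @return List with `data` (the filtered dataset) and `report`, a
#'   `"removal_report"`: per-cell counts (`cells`: subject, modality,
#'   target_id, n_before, n_removed, flagged) and per-modality removal
#'   fractions (`by_modality`).
#' @export
filter_outliers <- function(dataset, k = 3) {
  stopifnot(k > 0)
  key <- interaction(dataset$subject, dataset$modality, dataset$target_id,
                     drop = TRUE)
  idx <- split(seq_len(nrow(dataset)), key)
  keep <- rep(TRUE, nrow(dataset))
  cells <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    n <- length(i)
    flagged <- n < 3
    removed <- 0L
    if (!flagged) {
      x <- dataset$x_deg[i]; y <- dataset$y_deg[i]
      sx <- stats::sd(x); sy <- stats::sd(y)
      out <- (sx > 0 & abs(x - mean(x)) > k * sx) |
             (sy > 0 & abs(y - mean(y)) > k * sy)
      removed <- sum(out)
      keep[i[out]] <- FALSE
    }
    cells[[j]] <- data.frame(subject = dataset$subject[i[1]],
                             modality = dataset$modality[i[1]],
                             target_id = dataset$target_id[i[1]],
                             n_before = n, n_removed = removed,
                             flagged = flagged)
  }
  cells <- do.call(rbind, cells)
  by_mod <- do.call(rbind, lapply(split(cells, cells$modality), function(d)
    data.frame(modality = d$modality[1],
               n_before = sum(d$n_before),
               n_removed = sum(d$n_removed),
               fraction = sum(d$n_removed) / sum(d$n_before))))
  rownames(by_mod) <- NULL
  filtered <- dataset[keep, , drop = FALSE]
  attr(filtered, "grid") <- attr(dataset, "grid")
  class(filtered) <- class(dataset)
  report <- structure(list(cells = cells, by_modality = by_mod, k = k),
                      class = "removal_report")
  list(data = filtered, report = report)
}

#' @export
print.removal_report <- function(x, ...) {
  cat(sprintf("Outlier screen (+/- %g SD per axis, single pass):\n", x$k))
  for (i in seq_len(nrow(x$by_modality)))
    cat(sprintf("  %-3s %5d removed of %6d (%.2f%%)\n",
                x$by_modality$modality[i], x$by_modality$n_removed[i],
                x$by_modality$n_before[i], 100 * x$by_modality$fraction[i]))
  if (any(x$cells$flagged))
    cat("  ", sum(x$cells$flagged), "cell(s) with < 3 responses passed through\n")
  invisible(x)
}
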