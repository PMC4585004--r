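#' Read and write trial-level response datasets
#'
#' Responses are stored as comma-delimited text with header
#' `subject,modality,target_id,rep,x_deg,y_deg`; the target grid travels in a
#' sidecar file `<path>.grid` with header `target_id,az_deg,el_deg` (written
#' automatically, read when present). Writing then reading reproduces the
#' dataset exactly to full printed precision (coordinates are serialized with
#' 17 significant digits).
#'
#' @param path File path.
#' @param dataset A `"response_data"` data frame (see [simulate_responses()]).
#' @param grid_path Sidecar path; defaults to `<path>.grid`.
#' @return `read_responses()` returns a `"response_data"` data frame with the
#'   grid attached when a sidecar is found; `write_responses()` returns
#'   `path` invisibly.
#' @export
read_responses <- function(path, grid_path = paste0(path, ".grid")) {
  required <- c("subject", "modality", "target_id", "rep", "x_deg", "y_deg")
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject = "character",
                                        modality = "character")[
                           intersect(c("subject", "modality"),
                                     scan(path, what = "", nlines = 1, sep = ",",
                                          quiet = TRUE))])
  missing <- setdiff(required, names(dat))
  if (length(missing))
    stop("response file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  bad_mod <- !dat$modality %in% c("A", "V", "VA")
  if (any(bad_mod))
    stop("unknown modality at line(s) ",
         paste(utils::head(which(bad_mod) + 1L, 5), collapse = ", "),
         " of ", path, ": ",
         paste(unique(dat$modality[bad_mod]), collapse = ", "))
  bad_num <- !is.finite(dat$x_deg) | !is.finite(dat$y_deg) |
    !is.finite(dat$target_id) | !is.finite(dat$rep)
  if (any(bad_num))
    stop("malformed numeric field(s) at line(s) ",
         paste(utils::head(which(bad_num) + 1L, 5), collapse = ", "),
         " of ", path)
  key <- paste(dat$subject, dat$modality, dat$target_id, dat$rep)
  if (anyDuplicated(key))
    stop("duplicate (subject, modality, target, rep) records in ", path)
  if (file.exists(grid_path)) {
    g <- utils::read.csv(grid_path, stringsAsFactors = FALSE)
    if (!all(c("target_id", "az_deg", "el_deg") %in% names(g)))
      stop("grid sidecar ", grid_path,
           " must have columns target_id, az_deg, el_deg")
    class(g) <- c("target_grid", "data.frame")
    unknown <- setdiff(dat$target_id, g$target_id)
    if (length(unknown))
      stop("target_id(s) not in grid: ", paste(unknown, collapse = ", "))
    attr(dat, "grid") <- g
  }
  class(dat) <- c("response_data", "data.frame")
  dat
}

#' @rdname read_responses
#' @export
write_responses <- function(dataset, path, grid_path = paste0(path, ".grid")) {
  stopifnot(is.data.frame(dataset))
  out <- as.data.frame(dataset)[c("subject", "modality", "target_id", "rep",
                                  "x_deg", "y_deg")]
  out$x_deg <- sprintf("%.17g", out$x_deg)
  out$y_deg <- sprintf("%.17g", out$y_deg)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  g <- attr(dataset, "grid")
  if (!is.null(g))
    utils::write.csv(as.data.frame(g)[c("target_id", "az_deg", "el_deg")],
                     grid_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select a subset of responses by modality, hemifield, axis or eccentricity
#'
#' Target groupings follow the field's conventions: hemifields split on
#' elevation (`"upper"`: el > 0; `"lower"`: el < 0; `"HMP"`: el = 0, the
#' horizontal median plane; `"SMP"`: az = 0, the sagittal median plane);
#' axes group by direction (`"X"`: el = 0, `"Y"`: az = 0, `"XY"`: oblique
#' targets with |az| = |el| != 0).
#'
#' @param dataset A `"response_data"` data frame with an attached grid.
#' @param modality Optional modality filter (`"A"`, `"V"`, `"VA"`).
#' @param hemifield Optional: `"upper"`, `"lower"`, `"HMP"` or `"SMP"`.
#' @param axis Optional: `"X"`, `"Y"` or `"XY"`.
#' @param max_abs_az,max_eccentricity Optional upper bounds on |azimuth| and
#'   on radial eccentricity (degrees).
#' @return The matching records, grid attribute restricted accordingly; an
#'   empty selection is allowed but raised as a warning.
#' @export
select_subset <- function(dataset, modality = NULL, hemifield = NULL,
                          axis = NULL, max_abs_az = NULL,
                          max_eccentricity = NULL) {
  grid <- attr(dataset, "grid")
  if (is.null(grid)) stop("dataset has no attached target grid")
  keep <- rep(TRUE, nrow(grid))
  if (!is.null(hemifield)) {
    hemifield <- match.arg(hemifield, c("upper", "lower", "HMP", "SMP"))
    keep <- keep & switch(hemifield,
                          upper = grid$el_deg > 0,
                          lower = grid$el_deg < 0,
                          HMP = grid$el_deg == 0,
                          SMP = grid$az_deg == 0)
  }
  if (!is.null(axis)) {
    axis <- match.arg(axis, c("X", "Y", "XY"))
    keep <- keep & switch(axis,
                          X = grid$el_deg == 0,
                          Y = grid$az_deg == 0,
                          XY = abs(grid$az_deg) == abs(grid$el_deg) &
                            grid$az_deg != 0)
  }
  if (!is.null(max_abs_az)) keep <- keep & abs(grid$az_deg) <= max_abs_az
  if (!is.null(max_eccentricity))
    keep <- keep & target_eccentricity(grid$az_deg, grid$el_deg) <= max_eccentricity
  sub_grid <- grid[keep, , drop = FALSE]
  class(sub_grid) <- class(grid)
  rows <- dataset$target_id %in% sub_grid$target_id
  if (!is.null(modality)) rows <- rows & dataset$modality %in% modality
  out <- dataset[rows, , drop = FALSE]
  if (nrow(out) == 0) warning("selection is empty")
  attr(out, "grid") <- sub_grid
  class(out) <- class(dataset)
  out
}
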