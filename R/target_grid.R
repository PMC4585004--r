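#' Build a rectangular target grid in the 2D frontal field
#'
#' Targets are laid out on a regular azimuth x elevation lattice centred on
#' the fixation point (0, 0), with azimuth positive rightward and elevation
#' positive upward, both in degrees. The default is the 7 x 5 array at 10
#' degree spacing spanning +/-30 degrees azimuth and +/-20 degrees elevation.
#' Angular coordinates are treated as planar Euclidean coordinates throughout,
#' which is adequate over this field of view.
#'
#' @param n_az,n_el Odd number of azimuth columns / elevation rows.
#' @param spacing_deg Lattice spacing in degrees (> 0).
#' @return A data frame of class `"target_grid"` with columns `target_id`
#'   (integer, row-major: top elevation row first, azimuth left to right),
#'   `az_deg` and `el_deg`.
#' @examples
#' g <- target_grid()           # 35 targets
#' g25 <- drop_peripheral(g)    # the 25 retained for direction comparisons
#' @export
target_grid <- function(n_az = 7L, n_el = 5L, spacing_deg = 10) {
  if (n_az < 1L || n_el < 1L || n_az %% 2L == 0L || n_el %% 2L == 0L)
    stop("n_az and n_el must be odd and >= 1 (the grid needs a central target)")
  if (spacing_deg <= 0) stop("spacing_deg must be > 0")
  az <- spacing_deg * (seq_len(n_az) - (n_az + 1L) / 2L)
  el <- spacing_deg * rev(seq_len(n_el) - (n_el + 1L) / 2L)
  g <- expand.grid(az_deg = az, el_deg = el, KEEP.OUT.ATTRS = FALSE)
  g <- data.frame(target_id = seq_len(nrow(g)), az_deg = g$az_deg, el_deg = g$el_deg)
  attr(g, "spacing_deg") <- spacing_deg
  class(g) <- c("target_grid", "data.frame")
  g
}

#' Drop the most peripheral azimuth columns from a grid
#'
#' Direction comparisons require equal azimuth and elevation extents, so
#' targets beyond a cut-off eccentricity in azimuth are disregarded.
#'
#' @param grid A [target_grid()].
#' @param max_abs_az Retain targets with `|az| <= max_abs_az` (default 20).
#' @return The reduced grid (original ids preserved).
#' @export
drop_peripheral <- function(grid, max_abs_az = 20) {
  out <- grid[abs(grid$az_deg) <= max_abs_az, , drop = FALSE]
  attr(out, "spacing_deg") <- attr(grid, "spacing_deg")
  class(out) <- class(grid)
  out
}

#' Direction of a target from fixation
#'
#' @param az_deg,el_deg Target coordinates in degrees.
#' @return Direction in degrees, counterclockwise from the positive azimuth
#'   axis, in `[0, 360)`; `NA` for the fixation point itself, which has no
#'   defined direction.
#' @export
target_direction <- function(az_deg, el_deg) {
  d <- atan2(el_deg, az_deg) * 180 / pi
  d <- d %% 360
  d[az_deg == 0 & el_deg == 0] <- NA_real_
  d
}

#' Eccentricity of a target from fixation (degrees)
#' @inheritParams target_direction
#' @export
target_eccentricity <- function(az_deg, el_deg) sqrt(az_deg^2 + el_deg^2)

grid_lookup <- function(grid, target_id) {
  i <- match(target_id, grid$target_id)
  if (anyNA(i)) stop("unknown target_id: ",
                     paste(unique(target_id[is.na(i)]), collapse = ", "))
  grid[i, , drop = FALSE]
}
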