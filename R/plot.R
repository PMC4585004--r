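#' Plot a fitted localization field
#'
#' Base-graphics field maps in the style conventional for 2D pointing data:
#' `"ellipses"` draws the per-target confidence ellipses around the response
#' centroids; `"vectors"` draws the constant-error vectors from each target
#' to its centroid; `"distortion"` links centroids of adjacent targets to
#' show how faithfully the lattice topology is preserved.
#'
#' @param x A [locfield()] fit (or a `"locfield_pred"` via
#'   `plot_field_table()`).
#' @param which One of `"ellipses"`, `"vectors"`, `"distortion"`.
#' @param modality Condition to plot (default first available).
#' @param retained_only Restrict to retained targets (default TRUE).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-target table plotted.
#' @export
plot.locfield <- function(x, which = c("ellipses", "vectors", "distortion"),
                          modality = NULL, retained_only = TRUE, ...) {
  which <- match.arg(which)
  pt <- x$per_target
  if (retained_only) pt <- pt[pt$retained, ]
  if (is.null(modality)) modality <- pt$modality[1]
  pt <- pt[pt$modality == modality, ]
  plot_field_table(pt, which, x$grid, modality, ...)
}

plot_field_table <- function(pt, which, grid, modality, ...) {
  lim_x <- range(grid$az_deg) + c(-8, 8)
  lim_y <- range(grid$el_deg) + c(-8, 8)
  graphics::plot(NA, xlim = lim_x, ylim = lim_y, asp = 1,
                 xlab = "azimuth (deg)", ylab = "elevation (deg)",
                 main = paste(modality, "-", which), ...)
  graphics::points(pt$az_deg, pt$el_deg, pch = 3, col = "grey50")
  if (which == "ellipses") {
    tt <- seq(0, 2 * pi, length.out = 120)
    for (i in seq_len(nrow(pt))) {
      th <- pt$theta_deg[i] * pi / 180
      ex <- pt$a[i] * cos(tt) * cos(th) - pt$b[i] * sin(tt) * sin(th)
      ey <- pt$a[i] * cos(tt) * sin(th) + pt$b[i] * sin(tt) * cos(th)
      graphics::lines(pt$mu_x[i] + ex, pt$mu_y[i] + ey, col = "steelblue")
    }
    graphics::points(pt$mu_x, pt$mu_y, pch = 20, col = "steelblue")
  } else if (which == "vectors") {
    graphics::arrows(pt$az_deg, pt$el_deg, pt$mu_x, pt$mu_y,
                     length = 0.06, col = "firebrick")
  } else {
    cg <- data.frame(target_id = pt$target_id, x = pt$mu_x, y = pt$mu_y)
    keep <- grid$target_id %in% pt$target_id
    g <- grid[keep, , drop = FALSE]
    class(g) <- class(grid)
    attr(g, "spacing_deg") <- attr(grid, "spacing_deg")
    dg <- distortion_grid(cg, g)
    for (i in seq_len(nrow(dg$edges))) {
      p1 <- cg[match(dg$edges$from[i], cg$target_id), ]
      p2 <- cg[match(dg$edges$to[i], cg$target_id), ]
      graphics::segments(p1$x, p1$y, p2$x, p2$y, col = "darkgreen")
    }
    graphics::points(cg$x, cg$y, pch = 20, col = "darkgreen")
  }
  invisible(pt)
}
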