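#' Per-target bivariate response statistics
#'
#' A `dist_summary` holds the first two moments of a 2D response
#' distribution: centroid `mu_x`, `mu_y` (deg), per-axis variances `var_x`,
#' `var_y` (deg^2), covariance `cov_xy`, correlation `rho`, the 2D variance
#' `var_total = var_x + var_y` (whose square root is the variable error, VE,
#' in degrees), and the number of responses `n` (`Inf` for a closed-form
#' ground truth).
#'
#' @name dist_summary
#' @seealso [estimate_distribution()], [confidence_ellipse()]
NULL

dist_summary_from_moments <- function(mu, sigma, n, degenerate = FALSE) {
  vx <- sigma[1, 1]; vy <- sigma[2, 2]; cxy <- sigma[1, 2]
  rho <- if (vx > 0 && vy > 0) cxy / sqrt(vx * vy) else 0
  structure(list(mu_x = mu[1], mu_y = mu[2],
                 var_x = vx, var_y = vy, cov_xy = cxy,
                 rho = rho, var_total = vx + vy, n = n,
                 degenerate = degenerate || vx <= 0 || vy <= 0),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf("2D response distribution (n = %s)\n",
              if (is.infinite(x$n)) "exact" else x$n))
  cat(sprintf("  centroid (%.3f, %.3f) deg;  var (%.3f, %.3f), rho %.3f;  VE %.3f deg%s\n",
              x$mu_x, x$mu_y, x$var_x, x$var_y, x$rho, sqrt(x$var_total),
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' Covariance matrix of a distribution summary
#' @param x A [dist_summary].
#' @return 2 x 2 covariance matrix.
#' @export
cov_matrix <- function(x) {
  matrix(c(x$var_x, x$cov_xy, x$cov_xy, x$var_y), 2, 2)
}

#' Estimate a bivariate response distribution from pointing endpoints
#'
#' Unbiased (n - 1) sample moments of the 2D endpoints. A zero-variance axis
#' is flagged degenerate and the correlation, undefined there, is reported
#' as 0.
#'
#' @param x,y Response coordinates in degrees, or a two-column matrix as `x`.
#' @return A [dist_summary].
#' @examples
#' estimate_distribution(c(1, -1, 0, 0), c(0, 0, 1, -1)) # var 2/3 per axis
#' @export
estimate_distribution <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  if (n < 2) stop("at least 2 responses are required")
  if (length(y) != n) stop("x and y lengths differ")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("coordinates must be finite")
  mu <- c(mean(x), mean(y))
  vx <- stats::var(x); vy <- stats::var(y); cxy <- stats::cov(x, y)
  dist_summary_from_moments(mu, matrix(c(vx, cxy, cxy, vy), 2, 2), n = n)
}

#' Confidence ellipse of a bivariate response distribution
#'
#' The ellipse containing a given probability mass of the fitted normal:
#' semi-axes `a >= b` are `sqrt(lambda_i * q)` with `lambda_i` the covariance
#' eigenvalues and `q` the chi-square quantile on 2 df at `coverage`.
#' Orientation `theta_deg` is the axial angle of the leading eigenvector in
#' `[0, 180)` (an axis, not a direction). The anisotropy ratio `epsilon =
#' b/a` is 1 for circular scatter (no preferred direction) and approaches 0
#' for strongly oriented scatter; the squared-complement variant
#' `anisotropy_sq = 1 - (b/a)^2`, which inverts that reading, is also
#' reported for completeness.
#'
#' Degenerate cases: for circular covariance the orientation is undefined and
#' reported as 0 with `orientation_undefined = TRUE`; for a rank-1 covariance
#' `b = 0`, `epsilon = 0` and the orientation lies along the data axis.
#'
#' @param summary A [dist_summary].
#' @param coverage Probability mass, default 0.95.
#' @return An object of class `"ellipse"`: list with `a`, `b` (deg),
#'   `theta_deg`, `epsilon`, `anisotropy_sq`, `coverage`,
#'   `orientation_undefined`.
#' @export
confidence_ellipse <- function(summary, coverage = 0.95) {
  stopifnot(coverage > 0, coverage < 1)
  S <- cov_matrix(summary)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  q <- stats::qchisq(coverage, df = 2)
  a <- sqrt(lam[1] * q); b <- sqrt(lam[2] * q)
  undef <- isTRUE(all.equal(lam[1], lam[2])) || lam[1] <= 0
  theta <- if (undef) 0 else (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  eps <- if (a > 0) b / a else 0
  structure(list(a = a, b = b, theta_deg = theta,
                 epsilon = eps, anisotropy_sq = 1 - eps^2,
                 coverage = coverage, orientation_undefined = undef),
            class = "ellipse")
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("%.0f%% confidence ellipse: a = %.3f, b = %.3f deg, theta = %s, epsilon = %.3f\n",
              100 * x$coverage, x$a, x$b,
              if (x$orientation_undefined) "undefined" else sprintf("%.2f deg", x$theta_deg),
              x$epsilon))
  invisible(x)
}

#' Axial deviation between an ellipse orientation and a target direction
#'
#' Orientations are axes (theta and theta + 180 identified), so the deviation
#' is the absolute angular difference folded into `[0, 90]`.
#'
#' @param theta_deg Axial orientation(s), degrees.
#' @param direction_deg Target direction(s), degrees.
#' @return Deviation(s) in `[0, 90]`; `NA` where either input is `NA`
#'   (e.g. the fixation target, whose direction is undefined).
#' @export
axial_deviation <- function(theta_deg, direction_deg) {
  d <- abs(theta_deg - direction_deg) %% 180
  pmin(d, 180 - d)
}

#' Circular deviation between two directions
#'
#' @param alpha_deg,direction_deg Directions in degrees.
#' @return Absolute circular distance in `[0, 180]`.
#' @export
circular_deviation <- function(alpha_deg, direction_deg) {
  d <- abs(alpha_deg - direction_deg) %% 360
  pmin(d, 360 - d)
}
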