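#' Constant-error vector of a response distribution at a target
#'
#' The error vector runs from the target to the response centroid; its
#' length `r` is the constant error (CE, deg) and its direction `alpha` is
#' reported in `[0, 360)`. Two deviation measures relate `alpha` to the
#' target's own direction from fixation: `circular_dev` is the circular
#' distance in `[0, 180]` (180 = pure undershoot, the vector pointing back
#' toward fixation), and `axial_dev` folds that at 180 into `[0, 90]` (the
#' convention used for tabulated direction deviations, where undershoot and
#' overshoot along the target axis both count as 0).
#'
#' @param summary A [dist_summary].
#' @param az_deg,el_deg Target position (degrees).
#' @return Object of class `"error_vector"`: `dx`, `dy`, `r`, `alpha_deg`
#'   (`NA` when `r = 0`), `circular_dev`, `axial_dev` (`NA` for the fixation
#'   target, which has no direction), `target_direction`.
#' @examples
#' ev <- error_vector(estimate_distribution(c(8.8, 8.8), c(0, 0)), 10, 0)
#' ev$r          # 1.2
#' ev$alpha_deg  # 180: pure undershoot
#' @export
error_vector <- function(summary, az_deg, el_deg) {
  dx <- summary$mu_x - az_deg
  dy <- summary$mu_y - el_deg
  r <- sqrt(dx^2 + dy^2)
  alpha <- if (r == 0) NA_real_ else (atan2(dy, dx) * 180 / pi) %% 360
  tdir <- target_direction(az_deg, el_deg)
  cd <- if (is.na(tdir) || is.na(alpha)) NA_real_ else circular_deviation(alpha, tdir)
  structure(list(dx = dx, dy = dy, r = r, alpha_deg = alpha,
                 circular_dev = cd,
                 axial_dev = if (is.na(cd)) NA_real_ else pmin(cd, 180 - cd),
                 target_direction = tdir),
            class = "error_vector")
}

#' @export
print.error_vector <- function(x, ...) {
  cat(sprintf("error vector: r = %.3f deg, alpha = %s, deviation %s (circular) / %s (axial)\n",
              x$r,
              if (is.na(x$alpha_deg)) "undefined" else sprintf("%.2f deg", x$alpha_deg),
              if (is.na(x$circular_dev)) "NA" else sprintf("%.2f", x$circular_dev),
              if (is.na(x$axial_dev)) "NA" else sprintf("%.2f", x$axial_dev)))
  invisible(x)
}

#' Least-squares affine map from targets to response centroids
#'
#' Fits `centroid = M %*% target + t` by ordinary least squares over the
#' target set and decomposes the linear part as rotation o shear o scale
#' (via QR factorization, signs normalized so both scales are positive for a
#' proper map). The decomposition recomposes to `M` exactly; `rms_residual`
#' is the root-mean-square endpoint distance from the fitted map. A global
#' contraction of pointing space appears as `scale_x`, `scale_y` < 1 with
#' small rotation and shear.
#'
#' @param targets,centroids Two-column matrices (or data frames) of matched
#'   points, at least 3, not all collinear.
#' @return Object of class `"affine_map"`: `linear` (2 x 2), `translation`,
#'   `scale_x`, `scale_y`, `rotation_deg`, `shear`, `rms_residual`,
#'   `fitted`, `residuals`.
#' @export
fit_affine <- function(targets, centroids) {
  targets <- as.matrix(targets); centroids <- as.matrix(centroids)
  stopifnot(ncol(targets) == 2, ncol(centroids) == 2,
            nrow(targets) == nrow(centroids))
  if (nrow(targets) < 3) stop("at least 3 target/centroid pairs are required")
  X <- cbind(1, targets)
  if (qr(X)$rank < 3) stop("targets are collinear; the affine map is not identifiable")
  fit <- stats::lm.fit(X, centroids)
  B <- unname(fit$coefficients)
  translation <- as.numeric(B[1, ])
  M <- t(B[2:3, , drop = FALSE])  # M[i, j] = d centroid_i / d target_j
  dimnames(M) <- NULL
  qrM <- qr(M)
  Q <- qr.Q(qrM); R <- qr.R(qrM)
  # normalize so diag(R) > 0 where possible
  s <- sign(diag(R)); s[s == 0] <- 1
  Q <- Q %*% diag(s); R <- diag(s) %*% R
  if (det(Q) < 0) {  # improper map: put the reflection into scale_y
    Q[, 2] <- -Q[, 2]; R[2, ] <- -R[2, ]
  }
  res <- centroids - X %*% B
  structure(list(linear = M, translation = translation,
                 scale_x = R[1, 1], scale_y = R[2, 2],
                 shear = if (R[2, 2] != 0) R[1, 2] / R[2, 2] else 0,
                 rotation_deg = atan2(Q[2, 1], Q[1, 1]) * 180 / pi,
                 rms_residual = sqrt(mean(rowSums(res^2))),
                 fitted = X %*% B, residuals = res),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf(
    "affine target->endpoint map: scale (%.4f, %.4f), rotation %.3f deg, shear %.4f\n",
    x$scale_x, x$scale_y, x$rotation_deg, x$shear))
  cat(sprintf("  translation (%.3f, %.3f) deg; rms residual %.4f deg\n",
              x$translation[1], x$translation[2], x$rms_residual))
  invisible(x)
}

#' Local distortion grid linking centroids of adjacent targets
#'
#' Connects response centroids of 4-neighbour targets (one lattice step in
#' azimuth or elevation) and reports, per edge, the ratio of the response
#' edge length to the target edge length; ratios uniformly below 1 indicate
#' a global contraction of pointing space. Each unit lattice cell is also
#' checked for fold-over: a cell whose response quadrilateral has flipped
#' orientation relative to the target cell indicates a local topology
#' violation.
#'
#' @param centroids Data frame with columns `target_id`, `x`, `y` (response
#'   centroids, degrees).
#' @param grid The [target_grid()].
#' @return Object of class `"distortion_grid"`: `edges` (from, to,
#'   target_length, response_length, ratio), `cells` (corner ids and
#'   `folded` flag), `n_folded`, and `skipped` (edges dropped for missing
#'   centroids).
#' @export
distortion_grid <- function(centroids, grid) {
  spacing <- attr(grid, "spacing_deg")
  if (is.null(spacing)) {
    az <- sort(unique(grid$az_deg))
    spacing <- min(diff(az))
  }
  pos <- function(id) {
    i <- match(id, centroids$target_id)
    cbind(centroids$x[i], centroids$y[i])
  }
  has <- function(id) id %in% centroids$target_id
  neighbour <- function(az, el, daz, del) {
    j <- which(grid$az_deg == az + daz & grid$el_deg == el + del)
    if (length(j)) grid$target_id[j] else NA_integer_
  }
  edges <- list(); skipped <- integer(0); k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (d in list(c(spacing, 0), c(0, spacing))) {
      to <- neighbour(grid$az_deg[i], grid$el_deg[i], d[1], d[2])
      if (is.na(to)) next
      from <- grid$target_id[i]
      if (!has(from) || !has(to)) {
        skipped <- c(skipped, from)
        next
      }
      p1 <- pos(from); p2 <- pos(to)
      rl <- sqrt(sum((p2 - p1)^2))
      k <- k + 1L
      edges[[k]] <- data.frame(from = from, to = to,
                               target_length = spacing,
                               response_length = rl, ratio = rl / spacing)
    }
  }
  edges <- if (k) do.call(rbind, edges) else
    data.frame(from = integer(0), to = integer(0), target_length = numeric(0),
               response_length = numeric(0), ratio = numeric(0))
  cells <- list(); kc <- 0L
  shoelace <- function(p) {
    i2 <- c(2:nrow(p), 1)
    sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
  }
  for (i in seq_len(nrow(grid))) {
    az <- grid$az_deg[i]; el <- grid$el_deg[i]
    corner_ids <- c(grid$target_id[i],
                    neighbour(az, el, spacing, 0),
                    neighbour(az, el, spacing, spacing),
                    neighbour(az, el, 0, spacing))
    if (anyNA(corner_ids) || !all(has(corner_ids))) next
    p <- pos(corner_ids)
    kc <- kc + 1L
    cells[[kc]] <- data.frame(c1 = corner_ids[1], c2 = corner_ids[2],
                              c3 = corner_ids[3], c4 = corner_ids[4],
                              signed_area = shoelace(p),
                              folded = shoelace(p) <= 0)
  }
  cells <- if (kc) do.call(rbind, cells) else
    data.frame(c1 = integer(0), c2 = integer(0), c3 = integer(0),
               c4 = integer(0), signed_area = numeric(0), folded = logical(0))
  structure(list(edges = edges, cells = cells,
                 n_folded = sum(cells$folded),
                 skipped = unique(skipped)),
            class = "distortion_grid")
}

#' @export
print.distortion_grid <- function(x, ...) {
  cat(sprintf("distortion grid: %d edges, mean length ratio %.3f; %d folded cell(s)%s\n",
              nrow(x$edges), mean(x$edges$ratio), x$n_folded,
              if (length(x$skipped)) paste0("; skipped at target(s) ",
                                            paste(x$skipped, collapse = ", "))
              else ""))
  invisible(x)
}
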