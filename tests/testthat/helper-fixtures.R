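# small generators and constructors shared across tests

# a compact 3 x 3 grid for fast end-to-end runs
small_grid <- function() target_grid(3L, 3L, 10)

# moderate-dispersion profiles with known ground truth, light enough that
# centroids are recoverable at a few hundred reps
test_profiles <- function(outlier_rate = 0) {
  list(
    A = modality_profile(base_dispersion = 2.0, orientation_mode = "vertical",
                         axis_ratio = 0.4,
                         elevation_gain_upper = 0.6, elevation_gain_lower = 0.8,
                         horizon_offset_deg = 10, outlier_rate = outlier_rate),
    V = modality_profile(base_dispersion = 1.2, azimuth_slope = 0.02,
                         orientation_mode = "radial", axis_ratio = 0.5,
                         radial_gain_upper = 0.86, radial_gain_lower = 0.93,
                         elevation_gain_upper = 0.86, elevation_gain_lower = 0.93,
                         outlier_rate = outlier_rate)
  )
}

# a dist_summary directly from moments (exact, n responses nominal)
ds_from <- function(mu, sigma, n = 100) {
  locfuse:::dist_summary_from_moments(mu, sigma, n = n)
}

# random positive-definite 2x2 covariance with eigenvalues in [lo, hi]
random_pd <- function(lo = 0.2, hi = 4) {
  th <- stats::runif(1, 0, pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lam <- stats::runif(2, lo, hi)
  R %*% diag(lam) %*% t(R)
}

rotate_points <- function(x, y, phi_deg) {
  phi <- phi_deg * pi / 180
  list(x = x * cos(phi) - y * sin(phi),
       y = x * sin(phi) + y * cos(phi))
}
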