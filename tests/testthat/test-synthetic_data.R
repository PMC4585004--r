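test_that("ground-truth distributions encode the bias and covariance fields", {
  # visual-like radial contraction: gain 0.881 both hemifields
  v <- modality_profile(base_dispersion = 1.5, orientation_mode = "radial",
                        axis_ratio = 0.5,
                        radial_gain_upper = 0.881, radial_gain_lower = 0.881,
                        elevation_gain_upper = 0.881, elevation_gain_lower = 0.881)
  g <- ground_truth_distribution(v, 20, 0)
  expect_equal(c(g$mu_x, g$mu_y), c(17.62, 0))
  expect_equal(attr(g, "theta_deg"), 0)  # major axis along the target direction

  # fixation target: unbiased, orientation undefined, scatter circular
  g0 <- ground_truth_distribution(v, 0, 0)
  expect_equal(c(g0$mu_x, g0$mu_y), c(0, 0))
  expect_true(is.na(attr(g0, "theta_deg")))
  expect_equal(g0$var_x, g0$var_y)
  # total variance preserved in the circular limit
  expect_equal(g0$var_total, 1.5^2 * (1 + 0.5^2))

  # auditory-like vertical orientation at every target
  a <- modality_profile(base_dispersion = 2, orientation_mode = "vertical",
                        axis_ratio = 0.4)
  for (az in c(-20, 0, 20)) for (el in c(-10, 0, 10))
    expect_equal(attr(ground_truth_distribution(a, az, el), "theta_deg"), 90)
  # vertical: y variance is the major one
  ga <- ground_truth_distribution(a, 10, 10)
  expect_equal(ga$var_y, 4)
  expect_equal(ga$var_x, (0.4 * 2)^2)
})

test_that("simulated datasets have the study-scale structure and are seeded", {
  dat <- simulate_responses(n_subjects = 2, n_reps = 4, seed = 11)
  expect_s3_class(dat, "response_data")
  expect_equal(nrow(dat), 2 * 3 * 35 * 4)
  expect_equal(sum(dat$subject == "S01"), 3 * 35 * 4)
  expect_true(all(is.finite(dat$x_deg)))
  key <- paste(dat$subject, dat$modality, dat$target_id, dat$rep)
  expect_equal(anyDuplicated(key), 0L)

  dat2 <- simulate_responses(n_subjects = 2, n_reps = 4, seed = 11)
  expect_identical(dat, dat2)
  dat3 <- simulate_responses(n_subjects = 2, n_reps = 4, seed = 12)
  expect_false(identical(dat$x_deg, dat3$x_deg))
})

test_that("study-scale default run yields 10,500 records, 1,050 per subject", {
  dat <- simulate_responses(seed = 3)
  expect_equal(nrow(dat), 10500)
  expect_true(all(table(dat$subject) == 1050))
})

test_that("sample moments converge to the generating distribution", {
  g1 <- target_grid(1, 1, 10)
  g1$az_deg <- 20; g1$el_deg <- 10   # a single off-axis target
  profs <- test_profiles()
  n <- 10000
  dat <- simulate_responses(grid = g1, profiles = profs, n_subjects = 1,
                            n_reps = n, modalities = c("A", "V"), seed = 5)
  for (m in c("A", "V")) {
    gt <- ground_truth_distribution(profs[[m]], 20, 10)
    d <- dat[dat$modality == m, ]
    est <- estimate_distribution(d$x_deg, d$y_deg)
    # covariance elements within 5% relative of the generating values
    expect_lt(abs(est$var_x - gt$var_x) / gt$var_x, 0.05)
    expect_lt(abs(est$var_y - gt$var_y) / gt$var_y, 0.05)
    # zero-covariance cells are judged on the correlation scale
    expect_lt(abs(est$cov_xy - gt$cov_xy) /
                max(abs(gt$cov_xy), sqrt(gt$var_x * gt$var_y)), 0.05)
    # mean within 3 standard errors per axis
    expect_lt(abs(est$mu_x - gt$mu_x), 3 * sqrt(gt$var_x / n))
    expect_lt(abs(est$mu_y - gt$mu_y), 3 * sqrt(gt$var_y / n))
  }
})

test_that("exact-MLE bimodal generation respects the fusion inequality", {
  grid <- target_grid()
  profs <- default_profiles()
  for (i in seq_len(nrow(grid))) {
    gv <- ground_truth_distribution(profs$V, grid$az_deg[i], grid$el_deg[i])
    ga <- ground_truth_distribution(profs$A, grid$az_deg[i], grid$el_deg[i])
    f <- fuse_gaussians_2d(gv, ga)
    expect_lte(f$var_x, min(gv$var_x, ga$var_x) + 1e-12)
    expect_lte(f$var_y, min(gv$var_y, ga$var_y) + 1e-12)
    expect_lte(f$var_total, min(gv$var_total, ga$var_total) + 1e-12)
  }
})

test_that("permuting subject seeds permutes subjects without changing pooled moments", {
  grid <- small_grid()
  profs <- test_profiles()
  seeds <- c(101L, 202L, 303L)
  d1 <- simulate_responses(grid = grid, profiles = profs, n_subjects = 3,
                           n_reps = 6, modalities = c("A", "V"),
                           subject_seeds = seeds)
  d2 <- simulate_responses(grid = grid, profiles = profs, n_subjects = 3,
                           n_reps = 6, modalities = c("A", "V"),
                           subject_seeds = rev(seeds))
  # subject 1 of d1 is subject 3 of d2
  expect_equal(d1$x_deg[d1$subject == "S01"], d2$x_deg[d2$subject == "S03"])
  # pooled responses are identical as a set
  expect_equal(sort(d1$x_deg), sort(d2$x_deg))
  expect_equal(sort(d1$y_deg), sort(d2$y_deg))
})

test_that("missing profiles for a requested modality are rejected", {
  profs <- test_profiles()
  expect_error(simulate_responses(profiles = profs["V"], modalities = "A",
                                  n_subjects = 1, n_reps = 2, seed = 1),
               "profile")
  expect_error(simulate_responses(profiles = profs, modalities = "VA",
                                  bimodal_mode = "independent_profile",
                                  n_subjects = 1, n_reps = 2, seed = 1),
               "profile")
  # mle_exact only needs A and V
  d <- simulate_responses(grid = small_grid(), profiles = profs,
                          modalities = "VA", bimodal_mode = "mle_exact",
                          n_subjects = 1, n_reps = 2, seed = 1)
  expect_equal(unique(d$modality), "VA")
})
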