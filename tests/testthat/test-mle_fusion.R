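test_that("scalar fusion follows the reliability-weighting closed form", {
  f <- fuse_1d(0, 2, 1, 1)
  expect_equal(f$w_v, 0.5)
  expect_equal(f$var_fused, 0.5)
  expect_equal(f$r_fused, 1)

  f2 <- fuse_1d(1, 5, 1, 3)
  expect_equal(f2$w_v, 0.75)
  expect_equal(f2$var_fused, 0.75)
  expect_equal(f2$r_fused, 0.75 * 1 + 0.25 * 5)

  expect_error(fuse_1d(0, 0, 0, 1), "> 0")
})

test_that("the scalar fused estimate maximizes the product of likelihoods", {
  set.seed(8)
  for (rep in 1:20) {
    rv <- runif(1, -3, 3); ra <- runif(1, -3, 3)
    vv <- runif(1, 0.2, 4); va <- runif(1, 0.2, 4)
    f <- fuse_1d(rv, ra, vv, va)
    grid <- seq(min(rv, ra) - 1, max(rv, ra) + 1, by = 0.001)
    ll <- dnorm(grid, rv, sqrt(vv)) * dnorm(grid, ra, sqrt(va))
    expect_lt(abs(grid[which.max(ll)] - f$r_fused), 0.0011)
    # fused estimate lies between the two unimodal estimates
    expect_gte(f$r_fused, min(rv, ra) - 1e-12)
    expect_lte(f$r_fused, max(rv, ra) + 1e-12)
  }
})

test_that("2D fusion reproduces closed forms for simple cases", {
  # identical circular cues: halved variance, same mean
  d1 <- ds_from(c(0, 0), diag(2))
  f <- fuse_gaussians_2d(d1, d1)
  expect_equal(f$sigma, diag(2) / 2)
  expect_equal(f$mu, c(0, 0))
  expect_equal(f$w_v_x, 0.5)

  # independent axes: per-axis scalar fusion
  f2 <- fuse_gaussians_2d(ds_from(c(1, 0), diag(c(1, 4))),
                          ds_from(c(0, 1), diag(c(4, 1))))
  expect_equal(f2$mu, c(0.8, 0.8))
  expect_equal(f2$sigma, diag(c(0.8, 0.8)))
  expect_equal(f2$w_v_x, 0.8)
  expect_equal(f2$w_v_y, 0.2)

  # a vastly more reliable visual cue dominates
  f3 <- fuse_gaussians_2d(ds_from(c(1, 1), diag(2) * 1e-6),
                          ds_from(c(-3, 2), diag(2)))
  expect_equal(f3$mu, c(1, 1), tolerance = 1e-4)
  expect_gt(f3$w_v_x, 0.999)
})

test_that("fusion is commutative with swapped weights and tightens both parents", {
  set.seed(12)
  for (rep in 1:25) {
    dv <- ds_from(runif(2, -2, 2), random_pd())
    da <- ds_from(runif(2, -2, 2), random_pd())
    f1 <- fuse_gaussians_2d(dv, da)
    f2 <- fuse_gaussians_2d(da, dv)
    expect_equal(f1$mu, f2$mu, tolerance = 1e-12)
    expect_equal(f1$sigma, f2$sigma, tolerance = 1e-12)
    expect_equal(f1$w_v_x, f2$w_a_x, tolerance = 1e-12)
    expect_equal(f1$w_v_x + f1$w_a_x, 1)
    expect_equal(f1$w_v_y + f1$w_a_y, 1)
    # tightening: determinant, trace and marginals never exceed either parent
    Sv <- cov_matrix(dv); Sa <- cov_matrix(da)
    expect_lte(det(f1$sigma), min(det(Sv), det(Sa)) + 1e-12)
    expect_lte(sum(diag(f1$sigma)), min(sum(diag(Sv)), sum(diag(Sa))) + 1e-12)
    expect_lte(f1$var_x, min(Sv[1, 1], Sa[1, 1]) + 1e-12)
    expect_lte(f1$var_y, min(Sv[2, 2], Sa[2, 2]) + 1e-12)
  }
})

test_that("a singular covariance is regularized and flagged", {
  dv <- ds_from(c(0, 0), matrix(c(1, 1, 1, 1), 2, 2))
  f <- fuse_gaussians_2d(dv, ds_from(c(1, 1), diag(2)))
  expect_true(f$regularized)
  expect_true(all(is.finite(f$sigma)))
})

test_that("the quadrature oracle agrees with the closed form", {
  set.seed(99)
  for (rep in 1:20) {
    dv <- ds_from(runif(2, -1, 1), random_pd(0.3, 2.5))
    da <- ds_from(runif(2, -1, 1), random_pd(0.3, 2.5))
    f <- fuse_gaussians_2d(dv, da)
    o <- grid_product_oracle(dv, da, step = 0.05)
    expect_lt(max(abs(o$mu - f$mu)) / max(1, max(abs(f$mu))), 1e-4)
    expect_lt(max(abs(o$sigma - f$sigma)) / max(diag(f$sigma)), 1e-4)
  }
})

test_that("the oracle is converged: halving the step barely moves the moments", {
  dv <- ds_from(c(0.3, -0.2), matrix(c(1.2, 0.4, 0.4, 0.8), 2, 2))
  da <- ds_from(c(-0.1, 0.4), matrix(c(0.9, -0.2, -0.2, 1.5), 2, 2))
  o1 <- grid_product_oracle(dv, da, step = 0.05)
  o2 <- grid_product_oracle(dv, da, step = 0.025)
  expect_lt(max(abs(o1$mu - o2$mu)), 1e-6)
  expect_lt(max(abs(o1$sigma - o2$sigma)), 1e-6)
  # mirrored symmetric inputs fuse onto the x-axis
  dm1 <- ds_from(c(0.5, 1), diag(c(1, 2)))
  dm2 <- ds_from(c(0.5, -1), diag(c(1, 2)))
  om <- grid_product_oracle(dm1, dm2, step = 0.05)
  expect_lt(abs(om$mu[2]), 1e-8)
  expect_warning(grid_product_oracle(dv, da, n_sd = 4), "6 SD")
})

test_that("per-target field prediction behaves like an observed condition", {
  profs <- test_profiles()
  grid <- small_grid()
  sv <- sa <- list()
  for (i in seq_len(nrow(grid))) {
    k <- as.character(grid$target_id[i])
    sv[[k]] <- ground_truth_distribution(profs$V, grid$az_deg[i], grid$el_deg[i])
    sa[[k]] <- ground_truth_distribution(profs$A, grid$az_deg[i], grid$el_deg[i])
  }
  field <- predict_bimodal_field(sv, sa)
  expect_named(field, names(sv))
  for (k in names(field)) {
    expect_lte(field[[k]]$var_total,
               min(sv[[k]]$var_total, sa[[k]]$var_total) + 1e-12)
    # where both covariances are diagonal (on-axis targets here), each fused
    # mean coordinate is bracketed by the unimodal coordinates
    g <- grid[grid$target_id == as.integer(k), ]
    if (g$az_deg == 0 || g$el_deg == 0) {
      expect_gte(field[[k]]$mu[1] + 1e-9, min(sv[[k]]$mu_x, sa[[k]]$mu_x))
      expect_lte(field[[k]]$mu[1] - 1e-9, max(sv[[k]]$mu_x, sa[[k]]$mu_x))
      expect_gte(field[[k]]$mu[2] + 1e-9, min(sv[[k]]$mu_y, sa[[k]]$mu_y))
      expect_lte(field[[k]]$mu[2] - 1e-9, max(sv[[k]]$mu_y, sa[[k]]$mu_y))
    }
  }
  expect_error(predict_bimodal_field(sv[-1], sa), "match")
})
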