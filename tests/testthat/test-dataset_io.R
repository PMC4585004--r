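test_that("write then read round-trips a dataset exactly", {
  dat <- simulate_responses(grid = small_grid(), profiles = test_profiles(),
                            n_subjects = 2, n_reps = 3,
                            modalities = c("A", "V"), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(dat, path)
  back <- read_responses(path)
  expect_equal(back$x_deg, dat$x_deg)
  expect_equal(back$y_deg, dat$y_deg)
  expect_equal(back$subject, dat$subject)
  expect_equal(back$target_id, dat$target_id)
  expect_equal(as.data.frame(attr(back, "grid")),
               as.data.frame(attr(dat, "grid"))[c("target_id", "az_deg", "el_deg")],
               ignore_attr = TRUE)
})

test_that("schema violations are reported with names and line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,modality,target_id,rep,x_deg",
               "S01,V,1,0,1.5"), path)
  expect_error(read_responses(path), "y_deg")

  writeLines(c("subject,modality,target_id,rep,x_deg,y_deg",
               "S01,V,1,0,1.5,2.5",
               "S01,Q,1,1,1.5,2.5"), path)
  expect_error(read_responses(path), "line.*3")

  writeLines(c("subject,modality,target_id,rep,x_deg,y_deg",
               "S01,V,1,0,1.5,2.5",
               "S01,V,1,0,1.6,2.4"), path)
  expect_error(read_responses(path), "duplicate")
})

test_that("an empty file with a valid header reads as an empty dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject,modality,target_id,rep,x_deg,y_deg", path)
  d <- read_responses(path)
  expect_s3_class(d, "response_data")
  expect_equal(nrow(d), 0)
})

test_that("target groupings select the conventional subsets", {
  dat <- simulate_responses(n_subjects = 1, n_reps = 2,
                            modalities = "V", seed = 2)
  core <- select_subset(dat, max_abs_az = 20)
  expect_equal(nrow(attr(core, "grid")), 25)

  n_targets <- function(d) length(unique(attr(d, "grid")$target_id))
  expect_equal(n_targets(select_subset(core, hemifield = "upper")), 10)
  expect_equal(n_targets(select_subset(core, hemifield = "lower")), 10)
  expect_equal(n_targets(select_subset(core, hemifield = "HMP")), 5)
  expect_equal(n_targets(select_subset(core, hemifield = "SMP")), 5)
  expect_equal(n_targets(select_subset(core, axis = "X")), 5)
  expect_equal(n_targets(select_subset(core, axis = "Y")), 5)
  expect_equal(n_targets(select_subset(core, axis = "XY")), 8)

  # upper + lower + HMP partition the grid exactly
  ids <- sort(c(attr(select_subset(core, hemifield = "upper"), "grid")$target_id,
                attr(select_subset(core, hemifield = "lower"), "grid")$target_id,
                attr(select_subset(core, hemifield = "HMP"), "grid")$target_id))
  expect_equal(ids, sort(attr(core, "grid")$target_id))

  expect_warning(select_subset(core, modality = "VA"), "empty")
})

test_that("the outlier screen removes gross errors in well-filled cells only", {
  # a 20-trial cell: tight cluster plus one point far away -> exactly it removed
  set.seed(42)
  cell <- data.frame(subject = "S01", modality = "V", target_id = 1L,
                     rep = 0:19,
                     x_deg = c(rnorm(19, 0, 0.3), 15),
                     y_deg = c(rnorm(19, 0, 0.3), -12))
  res <- filter_outliers(cell)
  expect_equal(nrow(res$data), 19)
  expect_false(15 %in% res$data$x_deg)
  expect_equal(res$report$by_modality$n_removed, 1L)

  # a clean tight cell is untouched
  clean <- cell[1:19, ]
  res2 <- filter_outliers(clean)
  expect_equal(nrow(res2$data), 19)

  # cells below 3 trials pass through flagged
  tiny <- cell[1:2, ]
  res3 <- filter_outliers(tiny)
  expect_equal(nrow(res3$data), 2)
  expect_true(all(res3$report$cells$flagged))
})

test_that("a lone outlier is masked in a 10-trial cell (max z is (n-1)/sqrt(n))", {
  # the per-cell +/-3 SD rule cannot exceed z = 2.85 at n = 10, so even a
  # huge outlier survives; this is a property of the rule, not a bug
  cell <- data.frame(subject = "S01", modality = "A", target_id = 1L,
                     rep = 0:9,
                     x_deg = c(rep(0, 9) + seq(-0.04, 0.04, 0.01), 1e4),
                     y_deg = 0)
  res <- filter_outliers(cell)
  expect_equal(nrow(res$data), 10)
})

test_that("the screen is single-pass stable: a second pass removes no more than the first", {
  dat <- simulate_responses(grid = small_grid(),
                            profiles = test_profiles(outlier_rate = 0.05),
                            n_subjects = 2, n_reps = 30,
                            modalities = c("A", "V"), seed = 9)
  p1 <- filter_outliers(dat)
  p2 <- filter_outliers(p1$data)
  expect_lte(sum(p2$report$by_modality$n_removed),
             sum(p1$report$by_modality$n_removed))
  expect_gt(sum(p1$report$by_modality$n_removed), 0)
})

test_that("expected removal on clean Gaussian data matches the closed form", {
  # either-axis exceedance at k = 3: 1 - (1 - 2 pnorm(-3))^2 = 0.5396%
  set.seed(123)
  n <- 1e5
  cell <- data.frame(subject = "S01", modality = "V", target_id = 1L,
                     rep = seq_len(n) - 1L,
                     x_deg = rnorm(n), y_deg = rnorm(n))
  frac <- filter_outliers(cell)$report$by_modality$fraction
  expected <- 1 - (1 - 2 * pnorm(-3))^2
  expect_lt(abs(frac - expected), 4 * sqrt(expected / n))
})
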