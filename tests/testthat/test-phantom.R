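# Phantom: truth sampling, Rician rendering, cohort generation, splits.

test_that("truth maps reproduce the spec location in Monte-Carlo", {
  mask <- array(TRUE, c(22, 22, 22))  # 10648 voxels
  spec <- hcc_high_ki67_spec()
  tm <- sample_truth_maps(spec, mask, seed = 7)
  n <- sum(mask)
  for (par in c("ddc", "d", "adc")) {
    se <- spec$sd[[par]] / sqrt(n)
    expect_lt(abs(mean(tm$maps[[par]][mask]) - spec$location[[par]]), 2 * se)
  }
  # physical ranges hold by construction
  expect_true(all(tm$maps$f[mask] >= 0 & tm$maps$f[mask] <= 1))
  expect_true(all(tm$maps$alpha[mask] > 0 & tm$maps$alpha[mask] < 1))
  expect_true(all(tm$maps$d[mask] > 0))
})

test_that("zero spread gives constant truth maps and seeds reproduce", {
  mask <- test_mask()
  spec <- class_distribution_spec(
    location = c(adc = 1.3, d = 0.83, d_star = 59.48, f = 0.13,
                 ddc = 0.96, alpha = 0.65),
    spread = c(adc = 0, d = 0, d_star = 0, f = 0, ddc = 0, alpha = 0),
    afp_positive_rate = 0.5)
  tm <- sample_truth_maps(spec, mask, seed = 1)
  expect_true(all(tm$maps$ddc[mask] == 0.96))
  expect_true(all(tm$maps$f[mask] == 0.13))
  a <- sample_truth_maps(hcc_low_ki67_spec(), mask, seed = 33)
  b <- sample_truth_maps(hcc_low_ki67_spec(), mask, seed = 33)
  expect_identical(a, b)
  expect_error(sample_truth_maps(spec, array(FALSE, c(4, 4, 4))), "fewer")
})

test_that("noiseless rendering equals the forward model exactly", {
  mask <- test_mask()
  spec <- class_distribution_spec(
    location = c(adc = 1.0, d = 0.83, d_star = 59.48, f = 0.13,
                 ddc = 0.96, alpha = 0.65),
    spread = c(adc = 0, d = 0, d_star = 0, f = 0, ddc = 0, alpha = 0),
    afp_positive_rate = 0.5, s0 = 1)
  tm <- sample_truth_maps(spec, mask, seed = 2)
  ser <- render_dwi(tm, b9, model = "mono", sigma = 0)
  b1000 <- ser$signal[, , , 9]
  expect_equal(unique(b1000[mask]), exp(-1))
  expect_true(all(ser$signal[, , , 1][mask] == 1))
})

test_that("Rician corruption biases the baseline signal upward", {
  mask <- array(TRUE, c(20, 20, 10))
  spec <- class_distribution_spec(
    location = c(adc = 1, d = 0.8, d_star = 50, f = 0.1, ddc = 1,
                 alpha = 0.7),
    spread = c(adc = 0, d = 0, d_star = 0, f = 0, ddc = 0, alpha = 0),
    afp_positive_rate = 0.5, s0 = 1)
  tm <- sample_truth_maps(spec, mask, seed = 3)
  ser <- render_dwi(tm, b9, model = "mono", sigma = 0.05, seed = 9)
  expect_gt(mean(ser$signal[, , , 1][mask]), 1)  # magnitude bias
  expect_true(all(ser$signal >= 0))
})

test_that("cohorts are seeded, sized and AFP rates follow the spec", {
  co <- generate_cohort(n_high = 3, n_low = 2, seed = 5,
                        grid_dim = c(12, 12, 6))
  expect_length(co, 5)
  expect_identical(cohort_records(co)$ki67_high, c(1L, 1L, 1L, 0L, 0L))
  co2 <- generate_cohort(n_high = 3, n_low = 2, seed = 5,
                         grid_dim = c(12, 12, 6))
  expect_identical(co[[2]]$series$signal, co2[[2]]$series$signal)
  expect_identical(cohort_records(co), cohort_records(co2))
  expect_error(generate_cohort(n_high = 0, n_low = 5), ">= 1")

  # binomial expectation of AFP-positive counts at the class rates
  counts <- t(vapply(1:20, function(r) {
    rec <- cohort_records(generate_cohort(n_high = 46, n_low = 34,
                                          seed = 100 + r,
                                          grid_dim = c(10, 10, 5),
                                          axes_range = list(xy = c(2.8, 3.4),
                                                            z = c(1.6, 2.0)),
                                          sigma = 0))
    c(sum(rec$afp_high[rec$ki67_high == 1]),
      sum(rec$afp_high[rec$ki67_high == 0]))
  }, numeric(2)))
  expect_lt(abs(mean(counts[, 1]) - 24), 3)
  expect_lt(abs(mean(counts[, 2]) - 6), 2.5)
})

test_that("class-mean of fitted DDC scales with the spec location", {
  mask <- test_mask(c(10, 10, 4), c(3, 3, 1.6))
  base <- c(adc = 1, d = 0.8, d_star = 50, f = 0.1, ddc = 0.8, alpha = 0.7)
  fits <- vapply(c(1, 2), function(mult) {
    loc <- base; loc[["ddc"]] <- 0.8 * mult
    spec <- class_distribution_spec(location = loc,
                                    spread = 0.1 * loc, afp_positive_rate = 0.5)
    tm <- sample_truth_maps(spec, mask, seed = 40 + mult)
    pm <- fit_roi(render_dwi(tm, b9, model = "stretched", sigma = 0),
                  mask, models = "stretched")
    mean(map_values(pm, "ddc"))
  }, numeric(1))
  expect_equal(fits[2] / fits[1], 2, tolerance = 0.1)
})

test_that("stratified splits are disjoint, exhaustive and seeded", {
  df <- data.frame(subject = 1:10, ki67_high = rep(c(1, 0), each = 5))
  sp <- split_train_test(df, ratio = 0.5, seed = 3)
  expect_equal(nrow(sp$train), 5)
  expect_equal(nrow(sp$test), 5)
  expect_length(intersect(sp$train$subject, sp$test$subject), 0)
  expect_setequal(c(sp$train$subject, sp$test$subject), 1:10)
  # stratification holds within each class
  expect_equal(sum(sp$test$ki67_high), 2.5, tolerance = 0.5)
  sp2 <- split_train_test(df, ratio = 0.5, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_train_test(df, ratio = 0), "\\(0, 1\\)")
  tiny <- data.frame(ki67_high = c(1, 1, 0, 0))
  expect_error(split_train_test(tiny, ratio = 0.1), "empty")
})

test_that("feature-level cohorts reproduce the class-wise feature table", {
  d <- generate_feature_cohort(n_high = 400, n_low = 300, seed = 8)
  ref <- hcc_feature_reference()
  r <- ref[ref$map == "ddc" & ref$feature == "p5", ]
  sd_h <- r$high_spread / 1.349
  expect_lt(abs(mean(d$ddc_p5[d$ki67_high == 1]) - r$high_loc),
            3 * sd_h / sqrt(400) + 0.01)  # small clip bias allowed
  expect_lt(abs(mean(d$ddc_p5[d$ki67_high == 0]) - r$low_loc), 0.06)
  # exact AFP margins when requested
  de <- generate_feature_cohort(seed = 9, afp_exact = TRUE)
  expect_equal(sum(de$afp_high[de$ki67_high == 1]), 24)
  expect_equal(sum(de$afp_high[de$ki67_high == 0]), 6)
  expect_identical(generate_feature_cohort(seed = 10),
                   generate_feature_cohort(seed = 10))
})
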