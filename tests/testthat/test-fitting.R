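# Voxel fitters: closed forms, noise-free recovery, bound behaviour,
# degenerate inputs, and whole-ROI assembly.

test_that("two-point monoexponential fit is the closed form", {
  fit <- fit_mono(c(1, exp(-1.5)), c(0, 1000))
  expect_equal(coef(fit)[["adc"]], 1.5)
  expect_equal(coef(fit)[["s0"]], 1.0)
})

test_that("noiseless nine-point ADC recovery is exact", {
  fit <- fit_mono(mono_signal(b9, adc = 1.30, s0 = 100), b9)
  expect_equal(coef(fit)[["adc"]], 1.30, tolerance = 1e-12)
  expect_equal(coef(fit)[["s0"]], 100, tolerance = 1e-12)
  expect_false(fit$flagged)
})

test_that("degenerate monoexponential inputs are flagged", {
  expect_true(fit_mono(rep(1, 9), b9)$flagged)       # adc = 0
  expect_true(fit_mono(c(1, -1, rep(1, 7)), b9)$flagged)
  expect_true(fit_mono(exp(0.001 * unclass(b9)), b9)$flagged)  # increasing
})

test_that("noiseless biexponential recovery hits the truth within 1%", {
  s <- biexp_signal(b9, d = 0.83, d_star = 59.48, f = 0.13)
  fit <- fit_biexp(s, b9)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["d"]] / 0.83 - 1), 0.01)
  expect_lt(abs(coef(fit)[["d_star"]] / 59.48 - 1), 0.01)
  expect_lt(abs(coef(fit)[["f"]] / 0.13 - 1), 0.01)
})

test_that("monoexponential input degenerates the IVIM fit to f ~ 0", {
  fit <- fit_biexp(mono_signal(b9, adc = 0.83), b9)
  expect_lte(coef(fit)[["f"]], 1e-6)
  expect_equal(coef(fit)[["d"]], 0.83, tolerance = 1e-6)
})

test_that("D* truths outside the box are clamped exactly to the bounds", {
  up <- fit_biexp(biexp_signal(b9, d = 1, d_star = 500, f = 0.2), b9)
  expect_identical(coef(up)[["d_star"]], 200)
  lo <- fit_biexp(biexp_signal(b9, d = 0.4, d_star = 1.2, f = 0.3), b9)
  expect_identical(coef(lo)[["d_star"]], 3)
})

test_that("noiseless stretched-exponential recovery is within 0.5%", {
  s <- stretched_signal(b9, ddc = 0.96, alpha = 0.65)
  fit <- fit_stretched(s, b9)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["ddc"]] / 0.96 - 1), 0.005)
  expect_lt(abs(coef(fit)[["alpha"]] / 0.65 - 1), 0.005)
})

test_that("alpha = 1 input reduces the SEM fit to the mono fit", {
  s <- mono_signal(b9, adc = 0.96, s0 = 50)
  fit <- fit_stretched(s, b9)
  mono <- fit_mono(s, b9)
  expect_identical(coef(fit)[["alpha"]], 1)
  expect_equal(coef(fit)[["ddc"]], coef(mono)[["adc"]], tolerance = 1e-6)
})

test_that("constant signal degenerates the SEM fit to the DDC floor", {
  fit <- fit_stretched(rep(1, 9), b9)
  expect_true(fit$flagged)
})

test_that("optimizer matches the 0.1%-grid-search oracle on sample curves", {
  truths_b <- random_biexp_truth(5, seed = 91)
  for (i in seq_len(5)) {
    s <- biexp_signal(b9, truths_b$d[i], truths_b$d_star[i], truths_b$f[i])
    fit <- fit_biexp(s, b9)
    oracle <- grid_search_biexp(s, unclass(b9))
    expect_lte(fit$residual_norm, oracle$residual_norm + 1e-12)
  }
  truths_s <- random_sem_truth(5, seed = 92)
  for (i in seq_len(5)) {
    s <- stretched_signal(b9, truths_s$ddc[i], truths_s$alpha[i])
    fit <- fit_stretched(s, b9)
    oracle <- grid_search_stretched(s, unclass(b9))
    expect_lte(fit$residual_norm, oracle$residual_norm + 1e-12)
  }
})

test_that("fitted D* and alpha never leave their boxes under noise", {
  set.seed(77)
  truths <- random_biexp_truth(100, seed = 78)
  for (i in seq_len(100)) {
    s <- biexp_signal(b9, truths$d[i], truths$d_star[i], truths$f[i],
                      s0 = 100)
    s <- sqrt((s + rnorm(9, 0, 3))^2 + rnorm(9, 0, 3)^2)  # Rician, 3% of s0
    fb <- fit_biexp(s, b9)
    expect_gte(coef(fb)[["d_star"]], 3)
    expect_lte(coef(fb)[["d_star"]], 200)
    fs <- fit_stretched(s, b9)
    expect_gt(coef(fs)[["alpha"]], 0)
    expect_lte(coef(fs)[["alpha"]], 1)
  }
})

test_that("fit error degrades monotonically with noise level", {
  mask <- test_mask()
  sigmas <- c(0, 1, 2, 5)  # percent of s0 = 100
  med_d <- med_ddc <- numeric(length(sigmas))
  spec <- hcc_high_ki67_spec()
  for (k in seq_along(sigmas)) {
    truth_b <- sample_truth_maps(spec, mask, seed = 500 + k)
    ser_b <- render_dwi(truth_b, b9, model = "biexp", sigma = sigmas[k],
                        seed = 600 + k)
    pm_b <- suppressWarnings(fit_roi(ser_b, mask, models = "biexp"))
    med_d[k] <- median(abs(map_values(pm_b, "d") / truth_b$maps$d[mask] - 1),
                       na.rm = TRUE)
    truth_s <- sample_truth_maps(spec, mask, seed = 700 + k)
    ser_s <- render_dwi(truth_s, b9, model = "stretched", sigma = sigmas[k],
                        seed = 800 + k)
    pm_s <- suppressWarnings(fit_roi(ser_s, mask, models = "stretched"))
    ok <- !is.na(map_values(pm_s, "ddc", drop_na = FALSE))
    med_ddc[k] <- median(abs(map_values(pm_s, "ddc", drop_na = FALSE)[ok] /
                               truth_s$maps$ddc[mask][ok] - 1))
  }
  expect_true(all(diff(med_d) >= -1e-12))
  expect_true(all(diff(med_ddc) >= -1e-12))
})

test_that("whole-ROI fitting round-trips a noiseless biexponential phantom", {
  mask <- test_mask()
  truth <- sample_truth_maps(hcc_high_ki67_spec(), mask, seed = 21)
  series <- render_dwi(truth, b9, model = "biexp", sigma = 0)
  pm <- fit_roi(series, mask)
  expect_equal(pm$n_voxels, sum(mask))
  expect_true(all(abs(map_values(pm, "d") / truth$maps$d[mask] - 1) < 0.01))
  expect_true(all(abs(map_values(pm, "f") - truth$maps$f[mask]) < 0.01))
})

test_that("single-voxel masks and mismatched masks are handled", {
  mask <- array(FALSE, c(6, 6, 3)); mask[3, 3, 2] <- TRUE
  truth <- sample_truth_maps(hcc_high_ki67_spec(), mask, seed = 4)
  series <- render_dwi(truth, b9, sigma = 0)
  pm <- fit_roi(series, mask)
  expect_equal(pm$n_voxels, 1L)
  expect_equal(sum(!is.na(pm$maps$d)), 1L)
  expect_error(fit_roi(series, array(TRUE, c(7, 6, 3))), "grid")
})

test_that("unfittable voxels trigger the warning and error contracts", {
  mask <- array(TRUE, c(4, 4, 2))
  truth <- sample_truth_maps(hcc_high_ki67_spec(), mask, seed = 5)
  series <- render_dwi(truth, b9, sigma = 0)
  sig <- series$signal
  bad <- sample(which(mask), 12)  # ~38% of 32 voxels
  for (v in bad) sig[v + prod(dim(mask)) * 4] <- 0  # kill one b volume
  expect_warning(fit_roi(dwi_series(sig, b9), mask), "unfittable")
  sig[] <- 0
  expect_error(suppressWarnings(fit_roi(dwi_series(sig, b9), mask)),
               "all ROI voxels")
})

test_that("fit configuration rejects invalid settings", {
  expect_error(fit_config(dstar_bounds = c(200, 3)), "lower < upper")
  expect_error(fit_config(alpha_bounds = c(0.1, 0.9)), "alpha")
  expect_error(fit_biexp(rep(1, 4), c(0, 400, 600, 1000),
                         fit_config(ivim_split_b = 200)),
               "at/below")
})
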