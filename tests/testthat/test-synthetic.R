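test_that("the generator is deterministic under seed and seed-sensitive", {
  spec <- synthetic_spec(2.4e-4, 5.67, noise_sd = 0.01, seed = 42)
  a <- make_release_curve(spec)
  b <- make_release_curve(spec)
  expect_identical(a$values, b$values)
  spec2 <- synthetic_spec(2.4e-4, 5.67, noise_sd = 0.01, seed = 43)
  expect_false(identical(a$values, make_release_curve(spec2)$values))
  # the generator leaves the caller's RNG stream untouched
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(make_release_curve(spec))
  expect_identical(rnorm(1), before)
})

test_that("the noiseless forward models reproduce their closed forms and are monotone", {
  # sigma chosen so the square-root law has k_h = 5e-3 at d = 4
  d <- 4
  sigma <- (5e-3 * d / 2)^2
  spec <- synthetic_spec(sigma, d, noise_sd = 0, generator_model = "higuchi",
                         t_grid = c(1, 30, 100))
  rc <- make_release_curve(spec)
  expect_equal(release_fraction(rc)[3], 0.05, tolerance = 1e-14)

  spec_s <- synthetic_spec(2.4e-4, 5.67, noise_sd = 0)
  backbone <- release_fraction(make_release_curve(spec_s))
  expect_equal(backbone,
               series_oracle(spec_s$t_grid, 2.4e-4, 5.67, 2),
               tolerance = 1e-12)
  expect_true(all(diff(backbone) > 0))  # nondecreasing over default grid
})

test_that("noise draws land in the expected dispersion band and monotone mode flattens them", {
  spec0 <- synthetic_spec(2.4e-4, 5.67, t_grid = round(seq(30, 2800, length.out = 30)),
                          noise_sd = 0)
  spec1 <- synthetic_spec(2.4e-4, 5.67, t_grid = round(seq(30, 2800, length.out = 30)),
                          noise_sd = 0.01, seed = 42)
  resid <- release_fraction(make_release_curve(spec1)) -
    release_fraction(make_release_curve(spec0))
  expect_gt(sd(resid), 0.005)
  expect_lt(sd(resid), 0.02)

  spec_m <- synthetic_spec(2.4e-4, 5.67, noise_sd = 0.01, seed = 42,
                           monotone = TRUE)
  expect_true(all(diff(make_release_curve(spec_m)$values) >= 0))
})

test_that("film panels honour their ranges, ids and invariants", {
  p1 <- make_film_panel(1, sigma_range = c(2e-6, 2e-6),
                        d_range = c(5, 5), seed = 7)
  expect_equal(p1$truth$sigma_mm2_per_min, 2e-6 * 60, tolerance = 1e-12)
  expect_equal(p1$truth$thickness_mm, 5)

  p7 <- make_film_panel(7, seed = 42)
  expect_identical(length(unique(p7$truth$sample_id)), 7L)
  expect_true(all(p7$truth$sigma_mm2_per_min >= 0.181e-6 * 60 &
                    p7$truth$sigma_mm2_per_min <= 11.58e-6 * 60))
  expect_true(all(p7$truth$thickness_mm >= 2.07 &
                    p7$truth$thickness_mm <= 9.14))
  for (rc in p7$curves) {
    expect_s3_class(rc, "release_curve")
    expect_true(all(release_fraction(rc) >= 0))
  }
  expect_error(make_film_panel(3, sigma_range = c(2e-6, 1e-6)),
               class = "hydrokin_invalid_input")
  expect_error(make_film_panel(0), class = "hydrokin_invalid_input")
})

test_that("recovery_report computes per-film and aggregate relative errors", {
  truth <- data.frame(sample_id = c("a", "b"),
                      sigma_mm2_per_min = c(1e-4, 2e-4))
  rep0 <- recovery_report(truth, truth)
  expect_equal(rep0$per_film$rel_error, c(0, 0))
  expect_equal(rep0$max_abs_rel_error, 0)

  est <- transform(truth, sigma_mm2_per_min = sigma_mm2_per_min * c(1.1, 1))
  rep1 <- recovery_report(truth, est)
  expect_equal(sort(rep1$per_film$rel_error), c(0, 0.1), tolerance = 1e-12)
  expect_equal(rep1$median_abs_rel_error, 0.05, tolerance = 1e-12)

  bad <- data.frame(sample_id = c("a", "c"), sigma_mm2_per_min = c(1, 1))
  expect_error(recovery_report(truth, bad), class = "hydrokin_invalid_input")
})

test_that("matched generator and fitter give consistent estimation as noise vanishes", {
  panel <- make_film_panel(7, noise_sd = 0, seed = 42)
  est <- data.frame(
    sample_id = panel$truth$sample_id,
    sigma_mm2_per_min = vapply(seq_len(7), function(i) {
      fit_series(panel$curves[[i]], panel$truth$thickness_mm[i])$sigma
    }, numeric(1)))
  rep0 <- recovery_report(panel$truth, est)
  expect_lt(rep0$max_abs_rel_error, 1e-6)
})

test_that("mismatched generator and fitter reproduce the 1/pi bias", {
  # prefactored small-time series generator, bare square-root fitter
  spec <- synthetic_spec(3e-4, 5, truncation_n = 0L, noise_sd = 0,
                         t_grid = 1:30)
  rc <- make_release_curve(spec)
  sigma_hat <- diffusion_from_higuchi(fit_higuchi(rc), 5)$sigma_mm2_per_min
  expect_equal(sigma_hat / 3e-4, 1 / pi, tolerance = 0.01)
})
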