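test_that("stationary_density is real, matches hand values and solves the harmonic equation", {
  expect_identical(stationary_density(0, k = 1, amp = 1 + 0i), 2)
  expect_equal(stationary_density(0, k = 1, amp = 1i), 0)
  expect_equal(stationary_density(1, k = pi, amp = 1 + 0i), -2)
  # rho'' + k^2 rho = 0 via central second differences, O(h^2) accuracy
  k <- 2.3
  h <- 1e-3
  x <- seq(-2, 2, by = h)
  rho <- stationary_density(x, k, amp = 0.7 - 0.4i, phase = 0.9)
  sec <- (rho[-c(1, 2)] - 2 * rho[-c(1, length(rho))] +
            rho[-c(length(rho) - 1, length(rho))]) / h^2
  expect_lt(max(abs(sec + k^2 * rho[-c(1, length(rho))])), 1e-4)
})

test_that("Moebius maps act as fractional-linear transformations with the group law", {
  expect_identical(mobius_apply(2 + 3i, mobius(1, 0, 0, 1)), 2 + 3i)
  expect_identical(mobius_apply(1i, mobius(1, 1, 0, 1)), 1 + 1i)
  expect_error(mobius(1, 2, 2, 4), class = "hydrokin_invalid_input")
  expect_error(mobius_apply(-2, mobius(1, 1, 1, 2)),
               class = "hydrokin_invalid_input")  # pole at z = -d/c

  g <- mobius(3, 1, 2, 4, normalize = TRUE)
  expect_equal(g$a * g$d - g$b * g$c, 1, tolerance = 1e-14)

  # composition = matrix product, 100 seeded normalized draws
  set.seed(42)
  z <- complex(real = rnorm(1), imaginary = abs(rnorm(1)) + 0.5)
  for (i in 1:100) {
    p <- rnorm(8)
    if (abs(p[1] * p[4] - p[2] * p[3]) < 0.1) next
    if (abs(p[5] * p[8] - p[6] * p[7]) < 0.1) next
    g1 <- mobius(p[1], p[2], p[3], p[4])
    g2 <- mobius(p[5], p[6], p[7], p[8])
    lhs <- mobius_apply(mobius_apply(z, g1), g2)
    m <- matrix(c(p[5], p[7], p[6], p[8]), 2) %*%
      matrix(c(p[1], p[3], p[2], p[4]), 2)
    rhs <- (m[1, 1] * z + m[1, 2]) / (m[2, 1] * z + m[2, 2])
    expect_lt(Mod(lhs - rhs), 1e-10)
  }
})

test_that("z_harmonic matches closed forms and detects near-poles", {
  expect_equal(z_harmonic(0, 1.7), 1i, tolerance = 1e-15)
  expect_equal(z_harmonic(0, -3), 1i, tolerance = 1e-15)
  expect_equal(z_harmonic(1, 0), 1i * exp(-2), tolerance = 1e-14)
  # denominator modulus at alpha = pi is e^{-chi}; rounding keeps it above
  # the default mask in double precision, so exercise the guard explicitly
  expect_error(z_harmonic(12, pi, eps = 1e-4),
               class = "hydrokin_invalid_input")
})

test_that("z_pattern matches hand values, stays bounded and is pi/omega periodic", {
  expect_identical(z_pattern(0, 1, 0.37), complex(real = 0, imaginary = 1))
  expect_equal(z_pattern(0.5, 1, 0), 1i / 3, tolerance = 1e-15)
  expect_error(z_pattern(0.5, -1, 0), class = "hydrokin_invalid_input")
  # singular ring r = 1 at half-period phase is masked
  expect_true(is.na(z_pattern(1, 1, pi / 2)))

  set.seed(42)
  for (i in 1:100) {
    r <- runif(1, 0, 3)
    w <- runif(1, 0.5, 40)
    t <- runif(1, 0, 10)
    z1 <- z_pattern(r, w, t)
    z2 <- z_pattern(r, w, t + pi / w)
    # exact up to trig argument reduction at large omega*t
    if (!is.na(z1) && !is.na(z2)) expect_lt(Mod(z1 - z2), 1e-10)
  }

  # bounded with no masking on r in [0, 0.99]
  r <- seq(0, 0.99, length.out = 200)
  tt <- seq(0, 2 * pi, length.out = 200)
  m <- outer(r, tt, function(r, t) Mod(z_pattern(r, 1, t)))
  expect_false(anyNA(m))
  bound <- (1 + r^2) / (1 - r)^2
  expect_true(all(m <= bound + 1e-12))
})

test_that("the harmonic-map amplitude and the (r, omega t) form agree under r = coth(chi)", {
  # phase identification alpha = 2*omega*t; overall sign flips between forms
  set.seed(42)
  for (i in 1:100) {
    # chi <= 1.5 keeps r = coth(chi) >= 1.1, clear of the singular ring
    # r = 1 where Delta ~ (r-1)^2 amplifies argument-reduction noise
    chi <- runif(1, 0.1, 1.5)
    w <- runif(1, 0.5, 40)
    t <- runif(1, 0, 5)
    r <- 1 / tanh(chi)
    expect_lt(Mod(z_pattern(r, w, t) + z_harmonic(chi, 2 * w * t)), 1e-10)
  }
})

test_that("amplitude_map evaluates |z| on the grid with the omega rescaling identity", {
  m0 <- amplitude_map(3, r_grid = 0, t_grid = seq(0, 2, length.out = 11))
  expect_true(all(m0 == 1))
  m1 <- amplitude_map(2, r_grid = 0.5, t_grid = 0)
  expect_equal(as.numeric(m1), 1 / 3, tolerance = 1e-15)
  expect_error(amplitude_map(1, r_grid = numeric(0)),
               class = "hydrokin_invalid_input")
  # map at omega = 5 is the omega = 1 map with the t axis compressed 5x
  tg <- seq(0, 2, length.out = 50)
  rg <- seq(0, 0.9, length.out = 20)
  expect_equal(c(unclass(amplitude_map(5, rg, tg))),
               c(unclass(amplitude_map(1, rg, 5 * tg))), tolerance = 1e-14)
})

test_that("time traces are consistent, zero-mean in Re over a period, single-peaked in |z|", {
  tr0 <- time_traces(0, 2)
  expect_true(all(tr0$abs_z == 1) && all(tr0$re_z == 0) && all(tr0$im_z == 1))

  tr <- time_traces(0.7, 3)
  expect_equal(tr$abs_z^2, tr$re_z^2 + tr$im_z^2, tolerance = 1e-12)

  # mean of Re(z) over one full period vanishes (odd integrand)
  w <- 2.5
  r <- 0.6
  n <- 4096L
  tp <- seq(0, pi / w, length.out = n + 1L)[-(n + 1L)]
  expect_lt(abs(mean(Re(z_pattern(r, w, tp)))), 1e-10)
  quad <- integrate(function(t) Re(z_pattern(r, w, t)), 0, pi / w,
                    rel.tol = 1e-12, abs.tol = 1e-12)
  expect_lt(abs(quad$value), 1e-10)

  # |z| has exactly one strict maximum per period for every r != 1:
  # critical points satisfy cos(2wt) = -(1+r^2)/(2r), which lies outside
  # [-1, 1], so the modulus is monotone between the phase endpoints
  for (r in c(0.1, 0.5, 0.9, 1.5, 3)) {
    expect_identical(peak_count(r, 5), 1L)
  }
  # interaction-scale diagnostic: a fixed observation window holds
  # proportionally more |z| peaks at higher omega
  window_peaks <- function(w) {
    tt <- seq(0, 4 * pi, length.out = 20000L)
    y <- Mod(z_pattern(0.6, w, tt))
    sum(diff(sign(diff(y))) < 0)
  }
  expect_gt(window_peaks(5), window_peaks(1))
  expect_gt(window_peaks(39), window_peaks(5))
})

test_that("delay embedding produces lagged coordinates with the expected geometry", {
  e <- delay_embed(1:5, lag = 1, dim = 2)
  expect_equal(unclass(e)[, 1], c(1, 2, 3, 4), ignore_attr = TRUE)
  expect_equal(unclass(e)[, 2], c(2, 3, 4, 5), ignore_attr = TRUE)

  ec <- delay_embed(rep(2.5, 20), lag = 3, dim = 3)
  expect_identical(nrow(ec), 20L - 2L * 3L)  # count invariant
  expect_true(all(ec == 2.5))                # fixed point

  # sine embedded at quarter-period lag lies on the unit circle
  P <- 40L
  s <- sin(2 * pi * (0:400) / P)
  e2 <- delay_embed(s, lag = P / 4L, dim = 2)
  radii <- sqrt(e2[, 1]^2 + e2[, 2]^2)
  expect_lt(max(abs(radii - 1)), 1e-6)

  expect_error(delay_embed(1:5, lag = 3, dim = 3),
               class = "hydrokin_invalid_input")
  expect_error(delay_embed(1:5, lag = 0, dim = 2),
               class = "hydrokin_invalid_input")
})
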