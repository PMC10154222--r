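hat0 <- hat_curve(0, 3600, 10, 4, 4)

test_that("hat-curve fitting recovers the generating parameters", {
  d <- gen_hat_data(hat0, seed = 1)
  fit <- fit_hat_curve(d$turns, d$extension_nm)
  expect_equal(fit$plateau, hat0$plateau, tolerance = 0.05 * hat0$plateau)
  expect_equal(fit$center, hat0$center, tolerance = 0.5)
  expect_equal(fit$slope_left, hat0$slope_left,
               tolerance = 0.05 * hat0$slope_left)
  expect_equal(abs(fit$slope_right), abs(hat0$slope_right),
               tolerance = 0.05 * abs(hat0$slope_right))
  # mirror-symmetric input gives equal flank magnitudes within tolerance
  expect_equal(abs(fit$slope_left / fit$slope_right), 1, tolerance = 0.1)
  flat <- data.frame(turns = -40:40, extension_nm = rep(3000, 81))
  expect_error(fit_hat_curve(flat$turns, flat$extension_nm), "flank")
  one_side <- gen_hat_data(hat0, turns = seq(5, 40, 0.5), seed = 2)
  expect_error(fit_hat_curve(one_side$turns, one_side$extension_nm), "flank")
})

test_that("extension-to-turns inversion is the hat model inverse", {
  # round trip on each flank, noiseless
  for (br in c("minus", "plus")) {
    sgn <- if (br == "minus") -1 else 1
    state <- hat0$center + sgn * seq(5, 40, by = 0.25)
    ext <- hat_extension(hat0, state)
    relaxed <- turns_from_extension(ext, hat0, br, initial_turns = 40)
    truth <- 40 - abs(state - hat0$center)
    expect_lt(sqrt(mean((as.numeric(relaxed) - truth)^2)), 0.05)
  }
  # plateau extension maps to full relaxation (the initial offset), flagged
  top <- turns_from_extension(hat0$plateau + 10, hat0, "minus", 40)
  expect_equal(as.numeric(top), 40)
  expect_true(attr(top, "clipped"))
})

test_that("Savitzky-Golay smoothing has the right invariances", {
  t <- seq(0, 100, 0.1)
  quad <- 3 + 0.5 * t - 0.01 * t^2
  sm <- sg_smooth(quad, rate = 10, time_constant = 30)
  inner <- 200:800
  expect_equal(sm[inner], quad[inner], tolerance = 1e-8)
  expect_equal(sg_smooth(rep(7, 500), rate = 10), rep(7, 500),
               tolerance = 1e-10)
  # white-noise variance shrinks by the analytic order-2 SG factor
  set.seed(3)
  noise <- rnorm(5000)
  smn <- sg_smooth(noise, rate = 10, time_constant = 30)
  n_w <- 301
  m <- (n_w - 1) / 2
  gain <- 3 * (3 * m^2 + 3 * m - 1) / ((2 * m + 3) * (2 * m + 1) *
                                         (2 * m - 1))
  expect_equal(var(smn[500:4500]) / var(noise), gain, tolerance = 0.15)
  expect_error(sg_smooth(rnorm(100), rate = 10, time_constant = 30),
               "shorter")
})

test_that("dwell-time pause detection implements the binned procedure", {
  t <- seq(0, 200, 0.1)
  # constant-rate relaxation has no pauses
  ramp <- 0.8 * t
  expect_equal(nrow(detect_pauses(ramp, t)), 0)
  # two injected 30 s pauses at 10 and 20 turns
  x <- vapply(t, function(tt) {
    if (tt < 12.5) 0.8 * tt
    else if (tt < 42.5) 10
    else if (tt < 55) 10 + 0.8 * (tt - 42.5)
    else if (tt < 85) 20
    else 20 + 0.8 * (tt - 85)
  }, numeric(1))
  set.seed(4)
  xs <- sg_smooth(x + rnorm(length(x), 0, 0.4), rate = 10)
  pz <- detect_pauses(xs, t)
  expect_equal(nrow(pz), 2)
  expect_equal(pz$turn_level, c(10, 20), tolerance = 0.4)
  expect_equal(pz$duration, c(30, 30), tolerance = 0.2 * 30)
  expect_error(detect_pauses(1, 1), "short")
})

test_that("pause-free rate is the binned median over the first burst", {
  t <- seq(0, 30, 0.1)
  expect_equal(pause_free_rate(1.2 * t, t), 1.2, tolerance = 0.05)
  # invariant to pauses after the first burst
  t2 <- seq(0, 100, 0.1)
  x2 <- pmin(1.2 * t2, 24) + pmax(0, 1.2 * (t2 - 60))
  pz <- data.frame(turn_level = 24, start = 22, duration = 40)
  expect_equal(pause_free_rate(x2, t2, pz), 1.2, tolerance = 0.05)
  # doubling the noise moves the estimate by < 10%
  set.seed(6)
  n1 <- pause_free_rate(1.2 * t + rnorm(length(t), 0, 0.4), t)
  set.seed(6)
  n2 <- pause_free_rate(1.2 * t + rnorm(length(t), 0, 0.8), t)
  expect_lt(abs(n2 - n1) / n1, 0.1)
})

test_that("pause frequency comes from the censored exponential fit", {
  set.seed(7)
  draws <- rexp(200, 0.1)  # mean 10 turns before the first pause
  pf <- pause_frequency(draws, censor_turns = 1e6)
  expect_equal(pf$frequency, 0.1, tolerance = 0.15)
  # all-censored data report only the censoring floor, flagged
  none <- pause_frequency(rep(NA_real_, 20), censor_turns = 30)
  expect_true(none$upper_bound)
  expect_equal(none$frequency, 1 / 30)
  # frequency doubles when the underlying pause rate doubles
  set.seed(8)
  fast <- rexp(200, 0.2)
  pf2 <- pause_frequency(fast, censor_turns = 1e6)
  expect_equal(pf2$frequency / pf$frequency, 2, tolerance = 0.2)
  # censoring at 30 turns still recovers the rate from the observed range
  set.seed(9)
  cens <- pause_frequency(rexp(200, 0.1), censor_turns = 30)
  expect_equal(cens$frequency, 0.1, tolerance = 0.2)
  expect_error(pause_frequency(c(3, 5)), "at least")
})

test_that("mean relaxation rate counts pauses but stops at the plateau", {
  t <- seq(0, 100, 0.1)
  # no-pause trace: mean rate equals the pause-free rate within 5%
  ramp <- pmin(1.2 * t, 40)
  mr <- mean_relaxation_rate(ramp, t, initial_turns = 40)
  expect_true(mr$relaxed)
  expect_equal(mr$rate, pause_free_rate(ramp, t), tolerance = 0.05 * 1.2)
  # spending half the time paused halves the mean rate
  half <- vapply(t, function(tt) {
    if (tt < 16.5) 1.2 * tt else if (tt < 50) 19.8 else
      pmin(19.8 + 1.2 * (tt - 50), 40)
  }, numeric(1))
  mrh <- mean_relaxation_rate(half, t, initial_turns = 40)
  expect_equal(mrh$rate, 0.6, tolerance = 0.06)
  # never-relaxing trace is flagged with a near-zero rate
  stuck <- mean_relaxation_rate(rep(1, length(t)), t, initial_turns = 40)
  expect_false(stuck$relaxed)
  expect_lt(stuck$rate, 0.05)
})

test_that("trapped supercoil size converts plateau loss to base pairs", {
  expect_equal(trapped_loop_size(hat0, hat0)$loop_bp, 0)
  frac <- wlc_extension_at_force(0.22, el_ds)
  smaller <- hat_curve(0, hat0$plateau - 1000 * 0.338 * frac, 10, 4, 4)
  res <- trapped_loop_size(hat0, smaller, force = 0.22, el_ds)
  expect_equal(res$loop_bp, 1000, tolerance = 1)
  expect_false(res$inconsistent)
  # common vertical shifts of both hats cancel
  up1 <- hat_curve(0, hat0$plateau + 200, 10, 4, 4)
  up2 <- hat_curve(0, smaller$plateau + 200, 10, 4, 4)
  expect_equal(trapped_loop_size(up1, up2)$loop_bp, res$loop_bp,
               tolerance = 1e-9)
  bigger <- hat_curve(0, hat0$plateau + 100, 10, 4, 4)
  expect_true(trapped_loop_size(hat0, bigger)$inconsistent)
})

test_that("injected 2-turn staircases survive the extension round trip", {
  sc <- twist_scenario(hat = hat0, noise_sd = 0, seed = 9)
  tr <- gen_twist_trace(sc)
  gt <- attr(tr, "ground_truth")
  relaxed <- as.numeric(turns_from_extension(tr, hat0, sc$branch,
                                             sc$initial_turns))
  truth <- stepfun(gt$events$time, c(0, gt$events$turns_relaxed))(tr$time_s)
  expect_lt(sqrt(mean((relaxed - truth)^2)), 0.2)
})
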