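make_trace <- function(loops = NULL, breakage = NA, seed = 1, rate = 10000,
                       noise = 0.3) {
  sc <- stretch_scenario(loops = loops, breakage_force_pN = breakage,
                         noise_sd = noise, rate = rate, seed = seed)
  gen_stretch_trace(sc, el_ds)
}

test_that("decimation and filtering preserve means and shrink noise", {
  # constant signal is unchanged
  tr <- fx_trace(seq(0, 1, 1e-4)[-1], rep(5, 1e4), rep(100, 1e4), 1e4)
  out <- decimate_and_filter(tr)
  expect_true(all(abs(out$force_pN - 5) < 1e-12))
  expect_equal(attr(out, "acquisition_rate"), 1000)
  expect_equal(nrow(out), 1000)
  # a ramp keeps its slope through 10 kHz -> 1 kHz block averaging
  ramp <- fx_trace(seq(0, 1, 1e-4)[-1], seq(0, 10, length.out = 1e4),
                   seq(0, 500, length.out = 1e4), 1e4)
  rout <- decimate_and_filter(ramp, window = 0.002)
  slope <- coef(lm(rout$force_pN ~ rout$time_s))[2]
  expect_equal(unname(slope), 10, tolerance = 1e-2)
  # white noise sd drops by sqrt(25) under the 25 ms boxcar at 1 kHz
  set.seed(8)
  noise <- fx_trace(seq(1e-3, 20, 1e-3), rnorm(20000), rep(0, 20000), 1000)
  nout <- decimate_and_filter(noise, target_rate = 1000)
  expect_equal(sd(nout$force_pN[100:19900]), 1 / 5, tolerance = 0.1)
  expect_error(decimate_and_filter(tr, window = 1e-3), "window")
})

test_that("rupture detection finds injected events within thresholds", {
  naked <- decimate_and_filter(make_trace(seed = 2))
  expect_equal(nrow(detect_ruptures(naked)), 0)
  loops <- data.frame(loop_bp = c(250, 200, 300),
                      rupture_force_pN = c(12, 20, 28))
  tr <- decimate_and_filter(make_trace(loops, seed = 3))
  ev <- detect_ruptures(tr)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$peak_force, c(12, 20, 28), tolerance = 0.5)
  expect_true(all(diff(ev$peak_time) > 0))
  # events above the 60 pN ceiling are excluded by the threshold rule
  hi <- decimate_and_filter(make_trace(
    data.frame(loop_bp = 300, rupture_force_pN = 55), seed = 4
  ))
  ev_hi <- detect_ruptures(hi, max_force = 50)
  expect_equal(nrow(ev_hi), 0)
  expect_error(detect_ruptures(tr[1:10, ]), "shorter")
})

test_that("loop sizing recovers released base pairs from contour change", {
  tr <- decimate_and_filter(make_trace(
    data.frame(loop_bp = 300, rupture_force_pN = 28), seed = 5
  ))
  ev <- detect_ruptures(tr)
  expect_equal(nrow(ev), 1)
  ls <- loop_size_of_event(tr, ev[1, ], el_ds)
  expect_false(ls$truncated)
  expect_equal(ls$released_bp, 300, tolerance = 10)
  # stacked releases resolved as two events sum to the released total
  tr2 <- decimate_and_filter(make_trace(
    data.frame(loop_bp = c(100, 150), rupture_force_pN = c(18, 24)), seed = 6
  ))
  ev2 <- detect_ruptures(tr2)
  expect_equal(nrow(ev2), 2)
  tot <- sum(vapply(seq_len(2), function(k) {
    loop_size_of_event(tr2, ev2[k, ], el_ds)$released_bp
  }, numeric(1)))
  expect_equal(tot, 250, tolerance = 15)
})

test_that("extension at the reference force tracks DNA compaction", {
  tr <- decimate_and_filter(make_trace(seed = 7))
  x05 <- extension_at_reference_force(tr, 0.5)
  expect_equal(x05,
               12688 * el_ds$rise_per_bp *
                 wlc_extension_at_force(0.5, el_ds),
               tolerance = 0.02 * 4000)
  # 20% contour reduction shows up as ~20% lower extension at 0.5 pN
  sc <- stretch_scenario(template_bp = round(12688 * 0.8), seed = 8)
  tr2 <- decimate_and_filter(gen_stretch_trace(sc, el_ds))
  expect_equal(extension_at_reference_force(tr2, 0.5) / x05, 0.8,
               tolerance = 0.05)
  expect_error(extension_at_reference_force(tr, 0), "positive")
  expect_error(extension_at_reference_force(tr, 500), "reaches")
})

test_that("breakage force is read before collapse and censored at escape", {
  tr <- decimate_and_filter(make_trace(breakage = 58, seed = 9))
  bk <- tether_breakage_force(tr)
  expect_false(bk$censored)
  expect_equal(bk$force, 58, tolerance = 1)
  # no break before the trap limit: censored at the escape force
  tr2 <- decimate_and_filter(make_trace(seed = 10))
  bk2 <- tether_breakage_force(tr2)
  expect_true(bk2$censored)
  expect_equal(bk2$force, 110, tolerance = 1)
})

test_that("survival fitting recovers exponential kinetics", {
  # pure exponential: t_half = tau log(2)
  d <- gen_survival_lifetimes(1, 20, 200, n = 300, seed = 12)
  m <- fit_survival(d$lifetime)
  expect_equal(m$t_half, 20 * log(2), tolerance = 0.15 * 20 * log(2))
  # mixture recovery within generous CIs at n = 150
  d2 <- gen_survival_lifetimes(0.7, 5, 200, n = 150, seed = 13)
  m2 <- fit_survival(d2$lifetime, d2$censored)
  expect_equal(m2$amplitude_1, 0.7, tolerance = 0.15)
  expect_equal(m2$tau_1, 5, tolerance = 2)
  expect_equal(m2$tau_2, 200, tolerance = 100)
  expect_equal(m2$survival(m2$t_half), 0.5, tolerance = 1e-6)
  # t_half scales exactly with the time unit
  m_ms <- fit_survival(d2$lifetime * 1000, d2$censored)
  expect_equal(m_ms$t_half / m2$t_half, 1000, tolerance = 1e-3)
  expect_error(fit_survival(rep(5, 20)), "degenerate")
  expect_error(fit_survival(rexp(5)), "at least")
})

test_that("released base pairs are conserved across a multi-loop trace", {
  loops <- data.frame(loop_bp = c(200, 300, 250),
                      rupture_force_pN = c(10, 22, 35))
  tr <- decimate_and_filter(make_trace(loops, seed = 14))
  ev <- detect_ruptures(tr)
  expect_equal(nrow(ev), 3)
  released <- sum(vapply(seq_len(nrow(ev)), function(k) {
    loop_size_of_event(tr, ev[k, ], el_ds)$released_bp
  }, numeric(1)))
  # initial contour + all released bp = template, within 2%
  pre <- which(tr$force_pN > 2 & tr$force_pN < 6 &
                 tr$time_s < ev$peak_time[1])
  c0 <- median(as.numeric(contour_length_from_point(tr$force_pN[pre],
                                                    tr$extension_nm[pre],
                                                    el_ds)))
  expect_equal(c0 + released, 12688, tolerance = 0.02 * 12688)
})
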