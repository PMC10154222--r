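test_that("trace conversion reproduces the generating baseline", {
  cu0 <- gen_unzip_curve(fixture_baseline, seed = 1, noise_sd = 0)
  tr <- unzip_curve_as_trace(cu0, arm_bp = 6000, el_ds, el_ss)
  cu <- to_unzip_curve(tr, full_length = 1000, arm_bp = 6000, el_ds, el_ss)
  # force column is carried through unchanged (only sub-threshold points drop)
  expect_identical(cu$force, tr$force_pN[tr$force_pN >= 1])
  # recovered bp track the baseline positions within a few bp
  ref <- approx(fixture_baseline$position, fixture_baseline$force_pN,
                xout = cu$bp_unzipped, rule = 2)$y
  expect_lt(sqrt(mean((cu$force - ref)^2)), 0.5)
  expect_lt(cu$flagged_fraction, 0.05)
})

test_that("cross-correlation alignment recovers constructed shifts", {
  cu <- gen_unzip_curve(fixture_baseline, seed = 2)
  self <- align_to_baseline(cu, fixture_baseline)
  expect_equal(self$aligned_offset, 0)
  shifted <- cu
  shifted$bp_unzipped <- shifted$bp_unzipped + 37
  back <- align_to_baseline(shifted, fixture_baseline)
  expect_equal(back$aligned_offset, -37)
  # alignment followed by the inverse shift is the identity
  expect_equal(back$bp_unzipped, cu$bp_unzipped, tolerance = 1e-9)
  flat <- data.frame(position = 0:1000, force_pN = rep(15, 1001))
  expect_error(align_to_baseline(cu, flat), "featureless|ambiguous")
})

test_that("alignment tolerates noise on shifted curves", {
  hits <- vapply(1:40, function(s) {
    cu <- gen_unzip_curve(fixture_baseline, seed = 100 + s, noise_sd = 1)
    cu$bp_unzipped <- cu$bp_unzipped + 23
    align_to_baseline(cu, fixture_baseline)$aligned_offset == -23
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("interaction range sums super-threshold runs before breakage", {
  naked <- gen_unzip_curve(fixture_baseline, seed = 3)
  expect_equal(interaction_range(naked, fixture_baseline), 0)
  one <- gen_unzip_curve(fixture_baseline,
                         data.frame(start_bp = 300, span_bp = 300,
                                    delta_pN = 5), seed = 4)
  expect_equal(interaction_range(one, fixture_baseline), 300, tolerance = 10)
  # two runs separated by a sub-threshold gap: the gap is not counted
  two <- gen_unzip_curve(fixture_baseline,
                         data.frame(start_bp = c(200, 500),
                                    span_bp = c(100, 150),
                                    delta_pN = c(6, 6)), seed = 5)
  expect_equal(interaction_range(two, fixture_baseline), 250, tolerance = 12)
  # invariant to a common vertical offset of curve and baseline
  off <- one
  off$force <- off$force + 3
  base_off <- fixture_baseline
  base_off$force_pN <- base_off$force_pN + 3
  expect_equal(interaction_range(off, base_off),
               interaction_range(one, fixture_baseline))
  expect_error(interaction_range(one), "baseline")
})

test_that("maximum rupture force reflects the strongest obstacle", {
  rise <- gen_unzip_curve(fixture_baseline,
                          data.frame(start_bp = 600, span_bp = 150,
                                     delta_pN = 24),
                          breakage_cap_pN = 39, seed = 6)
  expect_equal(max_rupture_force(rise), 39, tolerance = 0.8)
  naked <- gen_unzip_curve(fixture_baseline, seed = 7)
  expect_equal(max_rupture_force(naked), max(fixture_baseline$force_pN),
               tolerance = 1.5)
})

test_that("breakage probability uses the binomial error model", {
  mk <- function(broke) {
    cu <- gen_unzip_curve(fixture_baseline, seed = 8)
    if (broke) cu$breakage_position <- 400
    cu
  }
  none <- breakage_probability(replicate(50, mk(FALSE), simplify = FALSE))
  expect_equal(none$fraction, 0)
  expect_equal(none$sem, 0)
  all_b <- breakage_probability(replicate(10, mk(TRUE), simplify = FALSE))
  expect_equal(all_b$fraction, 1)
  expect_equal(all_b$sem, 0)
  mix <- breakage_probability(c(replicate(46, mk(TRUE), simplify = FALSE),
                                replicate(4, mk(FALSE), simplify = FALSE)))
  expect_equal(mix$fraction, 0.92)
  expect_equal(mix$sem, sqrt(0.92 * 0.08 / 50), tolerance = 1e-9)
  expect_equal(mix$sem, 0.038367, tolerance = 1e-4)
  # breaks at or beyond 80% of full length do not count
  late <- mk(TRUE)
  late$breakage_position <- 0.9 * late$full_length
  expect_equal(breakage_probability(list(late))$fraction, 0)
})

test_that("binomial sem agrees with a bootstrap at n = 50", {
  p_hat <- 0.6
  n <- 50
  set.seed(17)
  x <- c(rep(TRUE, 30), rep(FALSE, 20))
  boot <- vapply(1:1000, function(i) mean(sample(x, n, replace = TRUE)),
                 numeric(1))
  expect_equal(sqrt(p_hat * (1 - p_hat) / n), sd(boot), tolerance = 0.1)
})
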