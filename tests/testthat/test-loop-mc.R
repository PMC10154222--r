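test_that("chain construction honors discretization and the internal bend", {
  ch <- chain_configuration(100, bend_angle = 150)
  expect_equal(ch$n_segments, 20)
  expect_equal(ch$segment_length, 100 * 0.338 / 20)
  expect_silent(validate_chain(ch))
  # rigid 150-degree midpoint kink: end separation = contour * cos(75 deg)
  expect_equal(end_to_end_distance(ch), 100 * 0.338 * cos(75 * pi / 180),
               tolerance = 1e-9)
  expect_error(chain_configuration(100, bend_angle = 200))
})

test_that("bending energy matches a naive independent summation", {
  # straight chain has zero energy; the rigid bend contributes none
  expect_equal(bending_energy(chain_configuration(200)), 0)
  expect_equal(bending_energy(chain_configuration(200, bend_angle = 150)), 0)
  # a single joint bent by theta costs g (1 - cos theta)
  b <- 1.69
  theta <- 37 * pi / 180
  ch <- chain_configuration(10, segment_bp = 5)
  ch$vertices <- rbind(c(0, 0, 0), c(b, 0, 0),
                       c(b + b * cos(theta), b * sin(theta), 0))
  g <- el_ds$persistence_length / b
  expect_equal(bending_energy(ch, el_ds), g * (1 - cos(theta)),
               tolerance = 1e-9)
  # 100-joint random chain vs a naive R-side recomputation
  set.seed(5)
  ch <- chain_configuration(505, segment_bp = 5)
  for (i in 1:50) ch <- pivot_move(ch)
  naive <- local({
    seg <- diff(ch$vertices)
    g2 <- el_ds$persistence_length / ch$segment_length
    tot <- 0
    for (i in seq_len(nrow(seg) - 1)) {
      ctheta <- sum(seg[i, ] * seg[i + 1, ]) /
        (sqrt(sum(seg[i, ]^2)) * sqrt(sum(seg[i + 1, ]^2)))
      tot <- tot + g2 * (1 - ctheta)
    }
    tot
  })
  expect_equal(bending_energy(ch, el_ds), naive, tolerance = 1e-9)
})

test_that("bias spring constant evaluates the stiffness schedule exactly", {
  expect_equal(bias_spring_constant(100, 150), 0.7072, tolerance = 1e-4)
  # the ratio at fixed L cancels the shared factors: 55/25 exactly
  expect_equal(bias_spring_constant(100, 0) / bias_spring_constant(100, 150),
               2.2, tolerance = 1e-12)
  expect_error(bias_spring_constant(100, 275), "non-positive")
})

test_that("pivot proposals are rigid and preserve the bend", {
  ch <- chain_configuration(150, bend_angle = 150)
  same <- pivot_move(ch, angle = 0)
  expect_equal(same$vertices, ch$vertices, tolerance = 1e-12)
  set.seed(11)
  cur <- ch
  worst <- 0
  for (i in 1:2000) {
    cur <- pivot_move(cur)
    seg <- sqrt(rowSums(diff(cur$vertices)^2))
    worst <- max(worst, max(abs(seg - cur$segment_length)) /
                   cur$segment_length)
  }
  expect_lt(worst, 1e-9)
  expect_silent(validate_chain(cur))  # includes the bend-angle check
})

test_that("unbiased sampling of a single joint follows the Boltzmann law", {
  # two segments: u = cos(joint angle) has density g exp(-g(1-u)) / (1-e^-2g)
  ch <- chain_configuration(20, segment_bp = 10)
  expect_equal(ch$n_segments, 2)
  b <- ch$segment_length
  g <- el_ds$persistence_length / b
  w <- metropolis_run(ch, fast_mc(seed = 3, n_prod = 3e5),
                      umbrella_window(0, 0), el_ds)
  mid <- (head(w$breaks, -1) + tail(w$breaks, -1)) / 2
  u <- pmin(1, pmax(-1, mid^2 / (2 * b^2) - 1))
  p <- w$counts / sum(w$counts)
  mean_emp <- sum(p * u)
  norm <- 1 - exp(-2 * g)
  mean_true <- integrate(function(x) x * g * exp(-g * (1 - x)) / norm,
                         -1, 1)$value
  expect_equal(mean_emp, mean_true, tolerance = 0.01)
  # full-distribution check: total variation against exact per-bin masses
  cdf_u <- function(x) (exp(-g * (1 - x)) - exp(-2 * g)) / norm
  u_edges <- pmin(1, pmax(-1, w$breaks^2 / (2 * b^2) - 1))
  p_true <- pmax(0, diff(cdf_u(u_edges)))
  expect_lt(0.5 * sum(abs(p - p_true)), 0.02)
})

test_that("Monte Carlo runs are deterministic and conserve tracked energy", {
  ch <- chain_configuration(100, bend_angle = 150)
  w1 <- metropolis_run(ch, fast_mc(seed = 9), umbrella_window(10, 0.7), el_ds)
  w2 <- metropolis_run(ch, fast_mc(seed = 9), umbrella_window(10, 0.7), el_ds)
  expect_identical(w1$counts, w2$counts)
  expect_identical(w1$blocks, w2$blocks)
  w3 <- metropolis_run(ch, fast_mc(seed = 10), umbrella_window(10, 0.7), el_ds)
  expect_false(identical(w1$counts, w3$counts))
  expect_lt(w1$max_energy_drift, 1e-6)
  expect_gt(w1$acceptance, 0.01)
})

test_that("J-factor conversion reproduces the uniform-sphere concentration", {
  # one end uniform in a sphere of radius R about the other: J = 1/(N_A V)
  R <- 100
  r <- seq(0.25, R, by = 0.5)
  J <- j_factor_from_p0(3 * r^2 / R^3, r = r, r_capture = 2)
  J_analytic <- NM3_TO_NM * 3 / (4 * pi * R^3)
  expect_equal(J, J_analytic, tolerance = 1e-9)
  expect_equal(J, 396.42, tolerance = 1e-4)
  # doubling the support in r scales J at fixed relative r by 1/8
  J2 <- j_factor_from_p0(3 * r^2 / R^3 / 2, r = 2 * r, r_capture = 4)
  expect_equal(J2 / J, 1 / 8, tolerance = 1e-9)
  # zero density at capture means zero J; outside support errors
  expect_equal(j_factor_from_p0(c(0, 0, 1), r = c(1, 2, 3), r_capture = 2), 0)
  expect_error(j_factor_from_p0(c(1, 1), r = c(5, 6), r_capture = 2),
               "support")
})

test_that("J-factor curves are reproducible and obey stiffness limits", {
  st <- mc_settings(n_equil = 1e4, n_prod = 4e4, seed = 21)
  a <- j_factor_curve(c(100, 200), bend_angle = 150, settings = st)
  b <- j_factor_curve(c(100, 200), bend_angle = 150, settings = st)
  expect_identical(a$summary, b$summary)
  # stiff unbent 50 bp loop: J indistinguishable from zero
  stiff <- j_factor_curve(50, bend_angle = 0, settings = st)
  expect_lt(stiff$summary$J_nM, 1)
  # the 150-degree bend lowers the looping barrier: J_bent >> J_unbent
  unbent <- j_factor_curve(c(100, 200), bend_angle = 0, settings = st)
  expect_true(all(a$summary$J_nM > unbent$summary$J_nM))
})

test_that("two-population scaling recovers known mixture coefficients", {
  L <- c(50, 100, 200, 400, 600)
  ju <- data.frame(L_bp = L, J_nM = c(0.1, 2, 30, 180, 120))
  jb <- data.frame(L_bp = L, J_nM = c(900, 400, 80, 10, 2))
  set.seed(31)
  counts <- rpois(length(L), 2 * ju$J_nM + 3 * jb$J_nM)
  fit <- predict_loop_size_distribution(ju, jb,
                                        data.frame(loop_bp = L,
                                                   count = counts))
  expect_equal(fit$scale_unbent, 2, tolerance = 0.3)
  expect_equal(fit$scale_bent, 3, tolerance = 0.3)
  # pure-unbent data drive the bent coefficient to (non-negative) zero
  counts_u <- rpois(length(L), 5 * ju$J_nM)
  fit_u <- predict_loop_size_distribution(ju, jb,
                                          data.frame(loop_bp = L,
                                                     count = counts_u))
  expect_lt(fit_u$scale_bent, 0.2)
  expect_gte(fit_u$scale_bent, 0)
  expect_error(predict_loop_size_distribution(ju, jb,
                                              data.frame(loop_bp = L,
                                                         count = rep(0, 5))),
               "zero")
})
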