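#' Stretching scenario
#'
#' Parameters of a synthetic constant-velocity stretching experiment: a DNA
#' template with topoisomerase-trapped loops that rupture at prescribed
#' forces, optional terminal tether breakage, and Gaussian force noise.
#'
#' @param template_bp template length, bp (default 12688, a 12.7-kb tether).
#' @param loops data.frame with columns `loop_bp` and `rupture_force_pN`
#'   (forces in (1, 60]; total loop size below the template length), or NULL.
#' @param breakage_force_pN terminal breakage force, or NA for none.
#' @param velocity pulling velocity, nm/s (default 200).
#' @param noise_sd force noise at the acquisition rate, pN (default 0.3).
#' @param rate acquisition rate, Hz (default 1000).
#' @param seed integer seed.
#' @return object of class `stretch_scenario`.
#' @export
stretch_scenario <- function(template_bp = 12688, loops = NULL,
                             breakage_force_pN = NA, velocity = 200,
                             noise_sd = 0.3, rate = 1000, seed = 1) {
  if (is.null(loops)) {
    loops <- data.frame(loop_bp = numeric(0), rupture_force_pN = numeric(0))
  }
  stopifnot(template_bp > 0, velocity > 0, noise_sd >= 0, rate > 0)
  if (nrow(loops)) {
    if (any(loops$loop_bp <= 0)) stop("loop sizes must be positive")
    if (any(loops$rupture_force_pN <= 1 | loops$rupture_force_pN > 60)) {
      stop("rupture forces must lie in (1, 60] pN")
    }
    if (sum(loops$loop_bp) >= template_bp) {
      stop("total loop size must be below the template length")
    }
  }
  if (!is.na(breakage_force_pN) && nrow(loops) &&
      breakage_force_pN <= max(loops$rupture_force_pN)) {
    stop("breakage force must exceed all rupture forces")
  }
  structure(
    list(template_bp = template_bp,
         loops = loops[order(loops$rupture_force_pN), , drop = FALSE],
         breakage_force_pN = breakage_force_pN, velocity = velocity,
         noise_sd = noise_sd, rate = rate, seed = seed),
    class = "stretch_scenario"
  )
}

#' Generate a constant-velocity stretching trace
#'
#' Quasi-static synthesis: at each stage position the force solves the
#' modified Marko--Siggia relation for the currently stretched contour
#' (template minus still-trapped loops); when the noise-free force reaches a
#' loop's rupture force, that loop's base pairs rejoin the contour and the
#' force drops accordingly; an optional terminal breakage collapses the force
#' to zero. Gaussian force noise is added at the acquisition rate. The trace
#' and its ground-truth sidecar are deterministic given the scenario seed.
#'
#' @param scenario a [stretch_scenario()].
#' @param elasticity a [ds_dna_elasticity()].
#' @param start_force force at the first sample, pN (default 0.05).
#' @param end_force force at which pulling stops if nothing breaks, pN
#'   (default 110, the trap escape force).
#' @return an [fx_trace()] with attribute `ground_truth`: a list with
#'   `events` (data.frame: time, force, loop_bp), `breakage` (list or NULL)
#'   and the scenario.
#' @export
#' @examples
#' sc <- stretch_scenario(loops = data.frame(loop_bp = 300,
#'                                           rupture_force_pN = 28))
#' tr <- gen_stretch_trace(sc)
gen_stretch_trace <- function(scenario, elasticity = ds_dna_elasticity(),
                              start_force = 0.05, end_force = 110) {
  stopifnot(inherits(scenario, "stretch_scenario"))
  set.seed(scenario$seed)
  el <- elasticity
  rise <- el$rise_per_bp
  # force as a smooth function of normalized extension
  f_hi <- max(end_force,
              if (!is.na(scenario$breakage_force_pN)) {
                scenario$breakage_force_pN
              } else 0) + 5
  fgrid <- c(seq(1e-4, 1, length.out = 60), seq(1.2, f_hi, length.out = 240))
  xgrid <- wlc_extension_at_force(fgrid, el)
  force_of_xnorm <- stats::splinefun(c(0, xgrid), c(0, fgrid),
                                     method = "hyman")
  contour <- scenario$template_bp - sum(scenario$loops$loop_bp)
  dt <- 1 / scenario$rate
  dx <- scenario$velocity * dt
  x <- contour * rise * wlc_extension_at_force(start_force, el)
  pending <- scenario$loops
  t_now <- 0
  times <- list(); forces <- list(); exts <- list()
  events <- data.frame(time = numeric(0), force = numeric(0),
                       loop_bp = numeric(0))
  breakage <- NULL
  stop_force <- if (!is.na(scenario$breakage_force_pN)) {
    scenario$breakage_force_pN
  } else end_force
  repeat {
    f_next <- if (nrow(pending)) pending$rupture_force_pN[1] else stop_force
    f_next <- min(f_next, stop_force)
    x_trig <- contour * rise * wlc_extension_at_force(f_next, el)
    nstep <- max(1L, as.integer(ceiling((x_trig - x) / dx)))
    xs <- x + dx * seq_len(nstep)
    fs <- force_of_xnorm(xs / (contour * rise))
    ts <- t_now + dt * seq_len(nstep)
    times[[length(times) + 1]] <- ts
    forces[[length(forces) + 1]] <- fs
    exts[[length(exts) + 1]] <- xs
    x <- xs[nstep]; t_now <- ts[nstep]
    if (nrow(pending) && pending$rupture_force_pN[1] <= stop_force &&
        abs(f_next - pending$rupture_force_pN[1]) < 1e-12) {
      events <- rbind(events, data.frame(time = t_now, force = fs[nstep],
                                         loop_bp = pending$loop_bp[1]))
      contour <- contour + pending$loop_bp[1]
      pending <- pending[-1, , drop = FALSE]
    } else {
      if (!is.na(scenario$breakage_force_pN)) {
        breakage <- list(time = t_now, force = fs[nstep])
        tail_n <- as.integer(0.5 * scenario$rate)
        times[[length(times) + 1]] <- t_now + dt * seq_len(tail_n)
        forces[[length(forces) + 1]] <- rep(0, tail_n)
        exts[[length(exts) + 1]] <- rep(x, tail_n)
      }
      break
    }
  }
  force <- unlist(forces) + rnorm(length(unlist(forces)),
                                  sd = scenario$noise_sd)
  tr <- fx_trace(unlist(times), force, unlist(exts), scenario$rate,
                 metadata = list(kind = "constant-velocity stretch",
                                 seed = scenario$seed))
  attr(tr, "ground_truth") <- list(events = events, breakage = breakage,
                                   scenario = scenario)
  tr
}

#' Draw tether lifetimes from a two-component exponential mixture
#'
#' @param amplitude_1 weight of the fast component (in `[0, 1]`).
#' @param tau_1,tau_2 component time constants, s.
#' @param n number of tethers.
#' @param censor_time observation limit, s (draws beyond it are censored).
#' @param seed integer seed.
#' @return data.frame with columns `lifetime` and `censored`.
#' @export
gen_survival_lifetimes <- function(amplitude_1 = 0.7, tau_1 = 5,
                                   tau_2 = 200, n = 150,
                                   censor_time = Inf, seed = 1) {
  stopifnot(amplitude_1 >= 0, amplitude_1 <= 1, tau_1 > 0, tau_2 > 0, n >= 1)
  set.seed(seed)
  comp <- runif(n) < amplitude_1
  lt <- ifelse(comp, rexp(n, 1 / tau_1), rexp(n, 1 / tau_2))
  censored <- lt > censor_time
  lt[censored] <- censor_time
  data.frame(lifetime = lt, censored = censored)
}

#' Generate a synthetic unzipping curve
#'
#' Additively elevates a naked-DNA force baseline over protein-bound spans,
#' applies seeded Gaussian noise, and (optionally) breaks the tether at the
#' first position where the noise-free force reaches a cap.
#'
#' @param baseline data.frame with `position` and `force_pN` (e.g. from
#'   [equilibrium_unzip_baseline()]).
#' @param bound_regions data.frame with columns `start_bp`, `span_bp`,
#'   `delta_pN`, or NULL for a naked curve.
#' @param breakage_cap_pN tether breaks where noise-free force first reaches
#'   this value, or NA.
#' @param noise_sd force noise, pN (default 0.3).
#' @param samples_per_bp sampling density of the synthetic curve (default 5).
#' @param seed integer seed.
#' @return an [unzip_curve()] with attribute `ground_truth`.
#' @export
gen_unzip_curve <- function(baseline, bound_regions = NULL,
                            breakage_cap_pN = NA, noise_sd = 0.3,
                            samples_per_bp = 5, seed = 1) {
  set.seed(seed)
  full <- max(baseline$position)
  bp <- seq(0, full, by = 1 / samples_per_bp)
  f0 <- approx(baseline$position, baseline$force_pN, xout = bp,
               rule = 2)$y
  if (!is.null(bound_regions) && nrow(bound_regions)) {
    for (i in seq_len(nrow(bound_regions))) {
      b <- bound_regions[i, ]
      in_region <- bp >= b$start_bp & bp < b$start_bp + b$span_bp
      f0[in_region] <- f0[in_region] + b$delta_pN
    }
  }
  breakage_position <- NA_real_
  if (!is.na(breakage_cap_pN)) {
    hit <- which(f0 >= breakage_cap_pN)[1]
    if (!is.na(hit)) {
      breakage_position <- bp[hit]
      bp <- bp[seq_len(hit)]
      f0 <- f0[seq_len(hit)]
    }
  }
  f <- pmax(f0 + rnorm(length(f0), sd = noise_sd), 0.1)
  out <- unzip_curve(bp, f, full_length = full,
                     breakage_position = breakage_position)
  attr(out, "ground_truth") <- list(bound_regions = bound_regions,
                                    breakage_cap_pN = breakage_cap_pN,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Render an unzipping curve as a force-extension trace
#'
#' Forward series-elasticity construction: each (force, bp-unzipped) point
#' maps to the extension of the dsDNA arms plus two released ssDNA strands;
#' time follows from the unzipping stage velocity. Used to exercise
#' [to_unzip_curve()] round trips.
#'
#' @param curve an [unzip_curve()].
#' @param arm_bp dsDNA arm length, bp.
#' @param arms,ss elasticity models.
#' @param velocity stage velocity, nm/s (default 400).
#' @param rate acquisition rate, Hz (default 1000).
#' @return an [fx_trace()].
#' @export
unzip_curve_as_trace <- function(curve, arm_bp = 6000,
                                 arms = ds_dna_elasticity(),
                                 ss = ss_dna_elasticity(),
                                 velocity = 400, rate = 1000) {
  f <- curve$force
  j <- curve$bp_unzipped
  x_arms <- arm_bp * arms$rise_per_bp * wlc_extension_at_force(f, arms)
  x <- x_arms + 2 * j * ssdna_extension_per_nt(f, ss)
  # enforce a monotone stage coordinate, then resample uniformly in time
  xs <- cummax(x)
  tt <- (xs - xs[1]) / velocity
  keep <- c(TRUE, diff(tt) > 0)
  grid <- seq(0, max(tt), by = 1 / rate)
  fx_trace(grid,
           approx(tt[keep], f[keep], xout = grid, rule = 2)$y,
           approx(tt[keep], x[keep], xout = grid, rule = 2)$y,
           rate, metadata = list(kind = "unzipping"))
}

#' Twisting scenario
#'
#' Parameters of a synthetic magnetic-tweezers relaxation experiment:
#' catalytic strand-passage events remove 2 turns each (Poisson process at
#' `pause_free_rate / 2` events per second); after each event the enzyme
#' pauses with probability `pause_prob` for an exponentially distributed
#' duration; extension follows the hat curve on the declared flank with
#' Gaussian noise.
#'
#' @param hat a [hat_curve()] (default: plateau 3600 nm, curvature 10
#'   nm/turn^2, cap half-width 4 turns, i.e. flank slopes of 40 nm/turn).
#' @param initial_turns applied winding magnitude (default 40).
#' @param branch `"minus"` or `"plus"` flank.
#' @param pause_free_rate relaxation rate within bursts, turns/s.
#' @param pause_prob per-cycle pause probability.
#' @param pause_mean mean pause duration, s.
#' @param step_turns turns removed per catalytic event (2 for a type II
#'   topoisomerase).
#' @param noise_sd extension noise, nm (default 30).
#' @param rate acquisition rate, Hz (default 10).
#' @param duration recording length, s (default 900).
#' @param seed integer seed.
#' @return object of class `twist_scenario`.
#' @export
twist_scenario <- function(hat = hat_curve(0, 3600, 10, 4, 4),
                           initial_turns = 40,
                           branch = c("minus", "plus"),
                           pause_free_rate = 1.2, pause_prob = 0.1,
                           pause_mean = 30, step_turns = 2,
                           noise_sd = 30, rate = 10, duration = 900,
                           seed = 1) {
  branch <- match.arg(branch)
  stopifnot(initial_turns > 0, pause_free_rate > 0,
            pause_prob >= 0, pause_prob <= 1, pause_mean > 0,
            step_turns > 0, noise_sd >= 0, rate > 0, duration > 0)
  structure(
    list(hat = hat, initial_turns = initial_turns, branch = branch,
         pause_free_rate = pause_free_rate, pause_prob = pause_prob,
         pause_mean = pause_mean, step_turns = step_turns,
         noise_sd = noise_sd, rate = rate, duration = duration, seed = seed),
    class = "twist_scenario"
  )
}

#' Generate a magnetic-tweezers relaxation trace
#'
#' Simulates burst-and-pause supercoil relaxation per the scenario and
#' renders it as extension versus time through the hat-curve model. The
#' ground-truth sidecar records every catalytic event and pause.
#'
#' @param scenario a [twist_scenario()].
#' @return a [twist_trace()] with attribute `ground_truth`: list with
#'   `events` (data.frame: time, turns_relaxed), `pauses` (data.frame:
#'   level, start, duration), `first_pause_turns` (NA if none) and the
#'   scenario.
#' @export
#' @examples
#' tr <- gen_twist_trace(twist_scenario(seed = 7))
gen_twist_trace <- function(scenario) {
  stopifnot(inherits(scenario, "twist_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  lambda <- sc$pause_free_rate / sc$step_turns  # events per second
  t_now <- 0
  relaxed <- 0
  ev_t <- numeric(0); ev_s <- numeric(0)
  pz_level <- numeric(0); pz_start <- numeric(0); pz_dur <- numeric(0)
  while (t_now < sc$duration && relaxed < sc$initial_turns) {
    t_now <- t_now + rexp(1, lambda)
    if (t_now >= sc$duration) break
    relaxed <- min(relaxed + sc$step_turns, sc$initial_turns)
    ev_t <- c(ev_t, t_now); ev_s <- c(ev_s, relaxed)
    if (relaxed < sc$initial_turns && runif(1) < sc$pause_prob) {
      d <- rexp(1, 1 / sc$pause_mean)
      pz_level <- c(pz_level, relaxed)
      pz_start <- c(pz_start, t_now)
      pz_dur <- c(pz_dur, d)
      t_now <- t_now + d
    }
  }
  tgrid <- seq(0, sc$duration, by = 1 / sc$rate)
  relax_t <- stats::stepfun(ev_t, c(0, ev_s))(tgrid)
  sgn <- if (sc$branch == "minus") -1 else 1
  turn_state <- sc$hat$center + sgn * (sc$initial_turns - relax_t)
  ext <- hat_extension(sc$hat, turn_state) +
    rnorm(length(tgrid), sd = sc$noise_sd)
  tr <- twist_trace(tgrid, ext, sgn * sc$initial_turns, sc$rate,
                    metadata = list(kind = "supercoil relaxation",
                                    seed = sc$seed, branch = sc$branch))
  attr(tr, "ground_truth") <- list(
    events = data.frame(time = ev_t, turns_relaxed = ev_s),
    pauses = data.frame(level = pz_level, start = pz_start,
                        duration = pz_dur),
    first_pause_turns = if (length(pz_level)) pz_level[1] else NA_real_,
    scenario = sc
  )
  tr
}

#' Sample a noisy hat curve
#'
#' @param hat a [hat_curve()].
#' @param turns turn values to sample (default -40..40 in 0.5-turn steps).
#' @param noise_sd extension noise, nm.
#' @param seed integer seed.
#' @return data.frame with `turns` and `extension_nm`.
#' @export
gen_hat_data <- function(hat, turns = seq(-40, 40, by = 0.5),
                         noise_sd = 30, seed = 1) {
  set.seed(seed)
  data.frame(turns = turns,
             extension_nm = hat_extension(hat, turns) +
               rnorm(length(turns), sd = noise_sd))
}
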