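#' Hat-curve model
#'
#' Piecewise extension-versus-turns calibration of a torsionally constrained
#' DNA tether: a rounded (quadratic) plateau of curvature `a` joined
#' continuously to two linear plectonemic flanks. The left/right buckling
#' points sit at `center - w_left` / `center + w_right` and the flank slopes
#' are `a w_left` (rising) and `-a w_right` (falling).
#'
#' @param center turn of maximum extension.
#' @param plateau maximum extension, nm.
#' @param curvature plateau curvature, nm per turn^2 (> 0).
#' @param w_left,w_right half-widths of the rounded cap, turns (> 0).
#' @return object of class `hat_curve`.
#' @export
hat_curve <- function(center, plateau, curvature, w_left, w_right) {
  stopifnot(plateau > 0, curvature > 0, w_left > 0, w_right > 0)
  structure(
    list(center = center, plateau = plateau, curvature = curvature,
         w_left = w_left, w_right = w_right,
         slope_left = curvature * w_left,
         slope_right = -curvature * w_right,
         buckling_left = center - w_left,
         buckling_right = center + w_right),
    class = "hat_curve"
  )
}

#' @export
print.hat_curve <- function(x, ...) {
  cat(sprintf(
    "hat curve: plateau %.0f nm at turn %.2f, buckling at %+.2f / %+.2f, slopes %+.1f / %+.1f nm per turn\n",
    x$plateau, x$center, x$buckling_left, x$buckling_right,
    x$slope_left, x$slope_right
  ))
  invisible(x)
}

#' Hat-curve forward model
#'
#' @param hat a [hat_curve()].
#' @param turns applied turns (vectorized).
#' @return extension, nm.
#' @export
hat_extension <- function(hat, turns) {
  d <- turns - hat$center
  ext <- hat$plateau - 0.5 * hat$curvature * d^2
  left <- d < -hat$w_left
  right <- d > hat$w_right
  ext[left] <- hat$plateau - 0.5 * hat$curvature * hat$w_left^2 -
    hat$curvature * hat$w_left * (-d[left] - hat$w_left)
  ext[right] <- hat$plateau - 0.5 * hat$curvature * hat$w_right^2 -
    hat$curvature * hat$w_right * (d[right] - hat$w_right)
  ext
}

#' Fit a hat curve to extension-versus-turns data
#'
#' Least-squares fit of the piecewise rounded-plateau model (see
#' [hat_curve()]). The data must span both flanks.
#'
#' @param turns applied turns.
#' @param extension nm.
#' @return a [hat_curve()] with extra fields `residual_sd` and `fit`.
#' @export
fit_hat_curve <- function(turns, extension) {
  stopifnot(length(turns) == length(extension), length(turns) >= 10)
  if (sd(extension) < 1e-9 * max(1, abs(mean(extension)))) {
    stop("extension does not vary with turns: no flanks to fit")
  }
  # robust center start: turn with maximal locally averaged extension
  ord <- order(turns)
  tt <- turns[ord]; ee <- extension[ord]
  sm <- .runmean(ee, max(3L, length(ee) %/% 20))
  c0 <- tt[which.max(sm)]
  h0 <- max(sm)
  span <- diff(range(tt))
  if (min(tt) > c0 - span / 20 || max(tt) < c0 + span / 20) {
    stop("data cover only one flank of the hat curve")
  }
  lo_ext <- min(ee)
  a0 <- 8 * (h0 - lo_ext) / span^2
  fit <- minpack.lm::nlsLM(
    ee ~ hat_extension(hat_curve(c, h, a, wl, wr), tt),
    start = list(c = c0, h = h0, a = a0, wl = span / 6, wr = span / 6),
    lower = c(c = min(tt), h = 0, a = 1e-6, wl = 0.3, wr = 0.3),
    upper = c(c = max(tt), h = Inf, a = Inf, wl = span, wr = span),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- coef(fit)
  out <- hat_curve(cf[["c"]], cf[["h"]], cf[["a"]], cf[["wl"]], cf[["wr"]])
  if (min(tt) > out$buckling_left || max(tt) < out$buckling_right) {
    stop("data cover only one flank of the hat curve")
  }
  out$residual_sd <- sd(residuals(fit))
  out$fit <- fit
  out
}

#' Convert extension to turns relaxed
#'
#' Inverts the hat-curve model on the declared flank to recover the turn
#' state from extension, then reports the number of helical turns relaxed
#' since the start of the recording. The mapping is monotone on each flank;
#' extensions above the plateau are clipped to full relaxation and flagged.
#'
#' @param trace a [twist_trace()] (or numeric extension vector).
#' @param hat a [hat_curve()].
#' @param branch `"minus"` if the tether was wound to negative turns (left
#'   flank), `"plus"` for positive.
#' @param initial_turns magnitude of the applied winding (default 40).
#' @return numeric vector of turns relaxed (>= 0), with attribute `clipped`
#'   (logical vector).
#' @export
turns_from_extension <- function(trace, hat, branch = c("minus", "plus"),
                                 initial_turns = 40) {
  branch <- match.arg(branch)
  ext <- if (inherits(trace, "twist_trace")) trace$extension_nm else trace
  clipped <- ext >= hat$plateau
  d <- rep(0, length(ext))  # |turn state - center|
  cap_edge_l <- hat$plateau - 0.5 * hat$curvature * hat$w_left^2
  cap_edge_r <- hat$plateau - 0.5 * hat$curvature * hat$w_right^2
  if (branch == "minus") {
    in_cap <- !clipped & ext >= cap_edge_l
    d[in_cap] <- sqrt(2 * (hat$plateau - ext[in_cap]) / hat$curvature)
    on_flank <- !clipped & !in_cap
    d[on_flank] <- hat$w_left + (cap_edge_l - ext[on_flank]) /
      (hat$curvature * hat$w_left)
  } else {
    in_cap <- !clipped & ext >= cap_edge_r
    d[in_cap] <- sqrt(2 * (hat$plateau - ext[in_cap]) / hat$curvature)
    on_flank <- !clipped & !in_cap
    d[on_flank] <- hat$w_right + (cap_edge_r - ext[on_flank]) /
      (hat$curvature * hat$w_right)
  }
  relaxed <- pmax(0, pmin(initial_turns, initial_turns - d))
  structure(relaxed, clipped = clipped)
}

#' Savitzky-Golay smoothing
#'
#' Order-2 Savitzky--Golay filter over a fixed time constant, the low-pass
#' stage of the pause-detection chain.
#'
#' @param series numeric vector.
#' @param rate sampling rate, Hz (default 10).
#' @param time_constant window, s (default 30).
#' @param order polynomial order (default 2).
#' @return smoothed series of the same length.
#' @export
sg_smooth <- function(series, rate = 10, time_constant = 30, order = 2) {
  n <- as.integer(round(time_constant * rate))
  if (n %% 2 == 0) n <- n + 1L
  if (length(series) < n) stop("series shorter than the filter window")
  as.numeric(signal::sgolayfilt(series, p = order, n = n))
}

#' Dwell-time pause detection
#'
#' Implements the dwell-time pause detector: the (smoothed) turns-relaxed
#' series is binned into 0.2-turn intervals and the dwell time in each bin is
#' computed; clusters of adjacent bins with more than 2 s of dwell each are
#' merged into single pausing states; the pausing regions are mapped back to
#' the time domain by collecting the data points within 0.4 turns of each
#' state's level; finally level and duration are refined by averaging over
#' the assigned points.
#'
#' @param turns_relaxed smoothed turns-relaxed series (see [sg_smooth()]).
#' @param time time stamps, s (uniform sampling assumed).
#' @param bin_width turn bin, 0.2 by default.
#' @param min_dwell dwell threshold per bin, s (default 2).
#' @param assign_radius half-width for time-domain assignment, turns
#'   (default 0.4).
#' @param min_level,max_level only report states strictly inside this level
#'   range (defaults 0.5 and Inf); use them to exclude the pre-activity
#'   origin and the fully relaxed plateau, which are dwells but not pauses.
#' @return data.frame of class `pause_states` with columns `turn_level`,
#'   `start`, `duration`, `n_points`.
#' @export
detect_pauses <- function(turns_relaxed, time, bin_width = 0.2,
                          min_dwell = 2, assign_radius = 0.4,
                          min_level = 0.5, max_level = Inf) {
  stopifnot(length(turns_relaxed) == length(time))
  if (length(time) < 3) stop("series too short for pause detection")
  dt <- median(diff(time))
  bins <- floor(turns_relaxed / bin_width)
  dwell <- tapply(rep(dt, length(bins)), bins, sum)
  bin_id <- as.integer(names(dwell))
  qual <- dwell > min_dwell
  empty <- data.frame(turn_level = numeric(0), start = numeric(0),
                      duration = numeric(0), n_points = integer(0))
  class(empty) <- c("pause_states", "data.frame")
  if (!any(qual)) return(empty)
  qb <- bin_id[qual]
  qd <- as.numeric(dwell[qual])
  cluster <- cumsum(c(1L, diff(qb) > 1L))
  out <- lapply(split(seq_along(qb), cluster), function(ii) {
    level0 <- weighted.mean((qb[ii] + 0.5) * bin_width, qd[ii])
    sel <- abs(turns_relaxed - level0) <= assign_radius
    if (!any(sel)) return(NULL)
    data.frame(turn_level = mean(turns_relaxed[sel]),
               start = min(time[sel]),
               duration = sum(sel) * dt,
               n_points = sum(sel))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[out$turn_level > min_level & out$turn_level < max_level, ,
             drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pause_states", "data.frame")
  out
}

# rolling least-squares slope of x(t) over a centered window of w samples
.roll_slope <- function(time, x, w) {
  n <- length(x)
  w <- max(3L, as.integer(w))
  half <- w %/% 2
  cs_t <- cumsum(c(0, time)); cs_x <- cumsum(c(0, x))
  cs_tt <- cumsum(c(0, time^2)); cs_tx <- cumsum(c(0, time * x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  m <- hi - lo + 1
  st <- cs_t[hi + 1] - cs_t[lo]
  sx <- cs_x[hi + 1] - cs_x[lo]
  stt <- cs_tt[hi + 1] - cs_tt[lo]
  stx <- cs_tx[hi + 1] - cs_tx[lo]
  (m * stx - st * sx) / pmax(m * stt - st^2, .Machine$double.eps)
}

#' Pause-free relaxation rate
#'
#' Rate during the first activity burst: the raw turns-relaxed series is
#' filtered with a 5 s sliding window, the instantaneous rate is obtained
#' from a rolling linear fit over the same time constant, the rates inside
#' the first burst (from activity onset to the first pause) are binned into
#' 0.5-turn bins, and the median over bins is returned.
#'
#' @param turns_relaxed raw (unsmoothed) turns-relaxed series.
#' @param time time stamps, s.
#' @param pauses optional [detect_pauses()] output; the first burst ends at
#'   the first pause start.
#' @param filter_constant sliding-window time constant, s (default 5).
#' @param rate_bin turn bin for the median, turns (default 0.5).
#' @param onset_turns the burst is taken to start once this many turns have
#'   relaxed (default 0.5, skipping the pre-activity dwell at the origin).
#' @return pause-free rate, turns per s.
#' @export
pause_free_rate <- function(turns_relaxed, time, pauses = NULL,
                            filter_constant = 5, rate_bin = 0.5,
                            onset_turns = 0.5) {
  stopifnot(length(turns_relaxed) == length(time))
  dt <- median(diff(time))
  w <- max(3L, as.integer(round(filter_constant / dt)))
  sm <- .runmean(turns_relaxed, w)
  # the rolling linear fit over the 5 s window IS the low-pass stage: fitting
  # an already-filtered series would double the time constant and bias rates
  # low at burst edges
  inst <- .roll_slope(time, turns_relaxed, w)
  t_end <- if (!is.null(pauses) && nrow(pauses) > 0) min(pauses$start) else
    max(time)
  onset_idx <- which(sm >= onset_turns)[1]
  if (is.na(onset_idx)) stop("no activity burst before the first pause")
  burst <- which(time >= time[onset_idx] & time <= t_end)
  if (length(burst) < w) burst <- seq.int(onset_idx, min(length(time),
                                                         onset_idx + w))
  bins <- floor(sm[burst] / rate_bin)
  med_by_bin <- tapply(inst[burst], bins, median)
  median(as.numeric(med_by_bin))
}

#' Pause frequency from first-pause turn counts
#'
#' Fits a single exponential to the cumulative (survival) histogram of the
#' number of turns relaxed before the first pause; traces without a detected
#' pause are assigned the censoring value (about 30 turns, the onset of the
#' pre-buckling region of a 12.7-kb tether at 0.22 pN). The pause frequency
#' is the reciprocal of the fitted decay constant.
#'
#' @param first_pause_turns turns relaxed before the first pause, one value
#'   per trace; censored traces may be given as NA or as values >=
#'   `censor_turns`.
#' @param censor_turns censoring value, turns (default 30).
#' @param min_traces minimum number of traces (default 10).
#' @return list with `frequency` (per turn), `decay_turns`, `n`,
#'   `n_censored`, `upper_bound` (TRUE when every trace was censored and
#'   only the censoring floor can be reported).
#' @export
pause_frequency <- function(first_pause_turns, censor_turns = 30,
                            min_traces = 10) {
  x <- first_pause_turns
  x[is.na(x) | x >= censor_turns] <- censor_turns
  n <- length(x)
  if (n < min_traces) stop("need at least ", min_traces, " traces")
  n_cens <- sum(x >= censor_turns)
  if (n_cens == n) {
    return(list(frequency = 1 / censor_turns, decay_turns = censor_turns,
                n = n, n_censored = n_cens, upper_bound = TRUE))
  }
  grid <- seq(0, min(censor_turns - 1e-9, max(x[x < censor_turns]) + 1),
              length.out = 100)
  surv <- vapply(grid, function(g) mean(x > g), numeric(1))
  fit <- minpack.lm::nlsLM(
    surv ~ exp(-grid * f),
    start = list(f = 1 / max(mean(x), 1e-6)),
    lower = c(f = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  f <- coef(fit)[["f"]]
  list(frequency = f, decay_turns = 1 / f, n = n, n_censored = n_cens,
       upper_bound = FALSE)
}

#' Mean relaxation rate
#'
#' Total turns relaxed divided by the elapsed time from relaxation onset to
#' first reaching the relaxed plateau, pauses included. Traces that never
#' relax within the recording return the overall average with a flag.
#'
#' @param turns_relaxed smoothed turns-relaxed series.
#' @param time time stamps, s (onset at `time[1]`, i.e. when magnet rotation
#'   completed).
#' @param initial_turns applied winding magnitude (default 40).
#' @param plateau_margin turns short of full relaxation that still count as
#'   the plateau (default 1).
#' @return list with `rate` (turns/s) and `relaxed` (logical).
#' @export
mean_relaxation_rate <- function(turns_relaxed, time, initial_turns = 40,
                                 plateau_margin = 1) {
  stopifnot(length(turns_relaxed) == length(time))
  hit <- which(turns_relaxed >= initial_turns - plateau_margin)[1]
  if (is.na(hit)) {
    total <- max(time) - time[1]
    return(list(rate = max(turns_relaxed) / max(total, .Machine$double.eps),
                relaxed = FALSE))
  }
  elapsed <- time[hit] - time[1]
  list(rate = turns_relaxed[hit] / max(elapsed, .Machine$double.eps),
       relaxed = TRUE)
}

#' Trapped supercoil size from hat-curve height reduction
#'
#' The drop in plateau extension between the initial and final hat curves,
#' converted to base pairs through the worm-like-chain fractional extension
#' at the holding force.
#'
#' @param hat_before,hat_after [hat_curve()] models.
#' @param force holding force, pN (default 0.22).
#' @param elasticity a [ds_dna_elasticity()].
#' @param noise_floor nm; negative height changes beyond this are flagged
#'   inconsistent (default 20).
#' @return list with `loop_bp`, `delta_extension_nm`, `inconsistent`.
#' @export
trapped_loop_size <- function(hat_before, hat_after, force = 0.22,
                              elasticity = ds_dna_elasticity(),
                              noise_floor = 20) {
  dh <- hat_before$plateau - hat_after$plateau
  frac <- wlc_extension_at_force(force, elasticity)
  list(loop_bp = dh / (elasticity$rise_per_bp * frac),
       delta_extension_nm = dh,
       inconsistent = dh < -noise_floor)
}

#' Full relaxation-trace analysis
#'
#' Convenience pipeline chaining [turns_from_extension()], [sg_smooth()],
#' [detect_pauses()], [pause_free_rate()] and [mean_relaxation_rate()] for
#' one magnetic-tweezers trace.
#'
#' @param trace a [twist_trace()].
#' @param hat a [hat_curve()].
#' @param branch `"minus"` or `"plus"`.
#' @param initial_turns applied winding magnitude (default 40).
#' @param sg_constant Savitzky--Golay time constant, s (default 30).
#' @return list with `turns_raw`, `turns_smooth`, `pauses`,
#'   `pause_free_rate`, `mean_rate`, `first_pause_turns` (NA when no pause
#'   was detected).
#' @export
analyze_twist_trace <- function(trace, hat, branch = c("minus", "plus"),
                                initial_turns = 40, sg_constant = 30) {
  branch <- match.arg(branch)
  rate <- attr(trace, "acquisition_rate")
  raw <- as.numeric(turns_from_extension(trace, hat, branch, initial_turns))
  smooth <- sg_smooth(raw, rate = rate, time_constant = sg_constant)
  smooth <- pmax(0, pmin(initial_turns, smooth))
  # pause detection stops where the tether first reaches the relaxed
  # plateau: the terminal dwell there is completion, not a pause
  hit <- which(smooth >= initial_turns - 1)[1]
  upto <- if (is.na(hit)) length(smooth) else hit
  pauses <- detect_pauses(smooth[seq_len(upto)], trace$time_s[seq_len(upto)],
                          max_level = initial_turns - 1)
  pfr <- tryCatch(
    pause_free_rate(raw, trace$time_s, pauses),
    error = function(e) NA_real_
  )
  mr <- mean_relaxation_rate(smooth, trace$time_s, initial_turns)
  list(
    turns_raw = raw, turns_smooth = smooth, pauses = pauses,
    pause_free_rate = pfr, mean_rate = mr$rate, relaxed = mr$relaxed,
    first_pause_turns = if (nrow(pauses) > 0) min(pauses$turn_level) else
      NA_real_
  )
}
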