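# centered boxcar mean with window shrinkage at the edges
.runmean <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  if (width <= 1) return(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Decimate and low-pass filter a force-extension trace
#'
#' Block-averages the trace down to `target_rate` (10 kHz to 1 kHz in the
#' standard acquisition chain), then applies a sliding boxcar of the stated
#' window to force and extension.
#'
#' @param trace an [fx_trace()].
#' @param target_rate output rate, Hz (default 1000). Must not exceed the
#'   acquisition rate; non-integer decimation factors are rejected.
#' @param window smoothing window, s (default 0.025). Must cover at least 2
#'   samples at the target rate.
#' @return a filtered [fx_trace()] at `target_rate`.
#' @export
decimate_and_filter <- function(trace, target_rate = 1000, window = 0.025) {
  rate <- attr(trace, "acquisition_rate")
  if (rate < target_rate) stop("acquisition rate below target rate")
  fac <- rate / target_rate
  if (abs(fac - round(fac)) > 1e-8) {
    stop("acquisition rate must be an integer multiple of target rate")
  }
  fac <- as.integer(round(fac))
  n <- nrow(trace)
  if (fac > 1) {
    nb <- n %/% fac
    idx <- rep(seq_len(nb), each = fac)
    keep <- seq_len(nb * fac)
    tm <- tapply(trace$time_s[keep], idx, mean)
    fo <- tapply(trace$force_pN[keep], idx, mean)
    ex <- tapply(trace$extension_nm[keep], idx, mean)
  } else {
    tm <- trace$time_s; fo <- trace$force_pN; ex <- trace$extension_nm
  }
  wsamp <- round(window * target_rate)
  if (wsamp < 2) stop("smoothing window shorter than 2 samples")
  out <- fx_trace(as.numeric(tm), .runmean(as.numeric(fo), wsamp),
                  .runmean(as.numeric(ex), wsamp), target_rate,
                  attr(trace, "metadata"))
  attr(out, "ground_truth") <- attr(trace, "ground_truth")
  out
}

#' Detect loop-rupture events in a constant-velocity stretching trace
#'
#' Scans the filtered force series for local maxima between the lower (1 pN)
#' and upper (60 pN, excluding the overstretching regime) force thresholds
#' that are followed within a short window by a force drop of at least the
#' configured prominence and an extension gain, and that are not terminal
#' tether breaks (force collapsing to baseline without recovery).
#'
#' @param trace a filtered [fx_trace()] from [decimate_and_filter()].
#' @param min_force lower peak threshold, pN (default 1).
#' @param max_force upper peak threshold, pN (default 60).
#' @param drop_window window after the peak in which the drop must occur, s
#'   (default 0.1).
#' @param min_drop minimum force drop (and minimum rise above the local
#'   pre-peak minimum), pN (default 1).
#' @param min_extension_gain minimum extension increase across the drop, nm
#'   (default 10).
#' @return data.frame of class `rupture_events` with columns `peak_time`,
#'   `peak_force`, `peak_index`, `drop_force`.
#' @export
detect_ruptures <- function(trace, min_force = 1, max_force = 60,
                            drop_window = 0.1, min_drop = 1,
                            min_extension_gain = 10) {
  rate <- attr(trace, "acquisition_rate")
  wsamp <- max(2L, as.integer(round(drop_window * rate)))
  if (nrow(trace) <= wsamp) stop("trace shorter than the detection window")
  f <- trace$force_pN
  pk <- pracma::findpeaks(f, minpeakheight = min_force, zero = "+")
  out <- data.frame(peak_time = numeric(0), peak_force = numeric(0),
                    peak_index = integer(0), drop_force = numeric(0))
  if (!is.null(pk)) {
    n <- length(f)
    for (row in seq_len(nrow(pk))) {
      i <- pk[row, 2]
      peak <- f[i]
      if (peak > max_force) next
      # prominence over the local pre-peak minimum
      pre_lo <- max(1L, i - wsamp)
      if (peak - min(f[pre_lo:i]) < min_drop) next
      post <- f[(i + 1):min(n, i + wsamp)]
      j <- which(peak - post >= min_drop)[1]
      if (is.na(j)) next
      # extension must advance across the drop
      gain <- trace$extension_nm[min(n, i + j)] - trace$extension_nm[i]
      if (gain < min_extension_gain &&
          trace$extension_nm[min(n, i + wsamp)] - trace$extension_nm[i] <
            min_extension_gain) next
      # terminal break: force stays at baseline afterwards
      after <- f[min(n, i + j):n]
      if (max(after) < min_force) next
      out <- rbind(out, data.frame(peak_time = trace$time_s[i],
                                   peak_force = peak, peak_index = i,
                                   drop_force = peak - post[j]))
    }
  }
  out <- out[order(out$peak_index), , drop = FALSE]
  # one rupture produces one event: candidates within the same drop window
  # are noise maxima riding the approach to the true peak - keep the highest
  if (nrow(out) > 1) {
    grp <- cumsum(c(1L, diff(out$peak_index) > wsamp))
    keep <- unlist(lapply(split(seq_len(nrow(out)), grp), function(ii) {
      ii[which.max(out$peak_force[ii])]
    }))
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("rupture_events", "data.frame")
  out
}

#' Loop size released by a rupture event
#'
#' Converts the trace to contour length via the modified Marko--Siggia model
#' in windows before and after the force drop (excluding a guard band around
#' the drop itself) and reports the released DNA as the difference of the
#' window medians.
#'
#' @param trace a filtered [fx_trace()].
#' @param event one row of [detect_ruptures()] output (or a list with
#'   `peak_index`).
#' @param elasticity a [ds_dna_elasticity()].
#' @param window median window on each side, s (default 0.05).
#' @param guard excluded band around the drop, s (default 0.01).
#' @param force_cutoff reliability cutoff passed to
#'   [contour_length_from_point()].
#' @return list with `released_bp`, `contour_before`, `contour_after`,
#'   `truncated` (TRUE when the post-event window was cut short by the trace
#'   end or a tether break, in which case `released_bp` is NA).
#' @export
loop_size_of_event <- function(trace, event,
                               elasticity = ds_dna_elasticity(),
                               window = 0.05, guard = 0.01,
                               force_cutoff = 0.25) {
  rate <- attr(trace, "acquisition_rate")
  i <- event$peak_index
  w <- max(2L, as.integer(round(window * rate)))
  g <- max(1L, as.integer(round(guard * rate)))
  n <- nrow(trace)
  pre <- seq.int(max(1L, i - g - w), max(1L, i - g))
  post <- seq.int(min(n, i + g), min(n, i + g + w))
  med_contour <- function(idx) {
    ok <- trace$force_pN[idx] > force_cutoff
    if (!any(ok)) return(NA_real_)
    bp <- contour_length_from_point(trace$force_pN[idx][ok],
                                    trace$extension_nm[idx][ok],
                                    elasticity, force_cutoff)
    median(as.numeric(bp))
  }
  before <- med_contour(pre)
  after <- med_contour(post)
  truncated <- (i + g + w) > n || is.na(after) ||
    max(trace$force_pN[post]) < force_cutoff
  list(
    released_bp = if (truncated) NA_real_ else after - before,
    contour_before = before, contour_after = after, truncated = truncated
  )
}

#' Extension at a reference force
#'
#' Reads the extension at the first upward crossing of `f_ref`; the DNA
#' compaction metric uses `f_ref = 0.5` pN. To keep the estimate unbiased in
#' the presence of force noise (a raw first-crossing fires systematically
#' early on a slow ramp), the crossing is located on a locally averaged force
#' and both force and extension are regressed on time in a window around it;
#' the extension is then evaluated at the regression crossing time.
#'
#' @param trace an [fx_trace()].
#' @param f_ref reference force, pN (> 0).
#' @param window regression half-window, s (default 1.5).
#' @return extension in nm.
#' @export
extension_at_reference_force <- function(trace, f_ref = 0.5, window = 1.5) {
  if (f_ref <= 0) stop("f_ref must be positive")
  rate <- attr(trace, "acquisition_rate")
  f_sm <- .runmean(trace$force_pN, max(3L, as.integer(round(0.25 * rate))))
  up <- which(f_sm[-1] >= f_ref & f_sm[-length(f_sm)] < f_ref)
  if (!length(up)) {
    if (f_sm[1] >= f_ref) return(trace$extension_nm[1])
    stop("trace never reaches f_ref")
  }
  i <- up[1]
  sel <- which(abs(trace$time_s - trace$time_s[i]) <= window)
  if (length(sel) < 10) {
    return(trace$extension_nm[i])
  }
  tt <- trace$time_s[sel]
  cf <- coef(lm(trace$force_pN[sel] ~ tt))
  if (abs(cf[2]) < .Machine$double.eps) return(trace$extension_nm[i])
  t_star <- (f_ref - cf[1]) / cf[2]
  cx <- coef(lm(trace$extension_nm[sel] ~ tt))
  unname(cx[1] + cx[2] * t_star)
}

#' Tether breakage force
#'
#' The breakage force is the last force before the trace collapses to the
#' zero-tension baseline. Tethers that survive to the trap escape force are
#' censored at that force (a conservative lower bound).
#'
#' @param trace an [fx_trace()].
#' @param escape_force maximum trapping force, pN (default 110).
#' @param baseline force level regarded as zero tension, pN (default 1).
#' @return list with `force` (pN) and `censored` (logical).
#' @export
tether_breakage_force <- function(trace, escape_force = 110, baseline = 1) {
  f <- trace$force_pN
  n <- length(f)
  # a break: force falls below baseline and never recovers
  low <- which(f < baseline)
  low <- low[low > which.max(f >= baseline)]  # after tension is established
  brk <- NA_integer_
  for (i in low) {
    if (i > 1 && max(f[i:n]) < baseline + 0.5 && f[i - 1] >= baseline) {
      brk <- i
      break
    }
  }
  if (!is.na(brk)) {
    pre <- f[max(1, brk - 50):(brk - 1)]
    return(list(force = max(pre), censored = FALSE))
  }
  if (max(f) >= escape_force) {
    return(list(force = escape_force, censored = TRUE))
  }
  list(force = max(f), censored = TRUE)
}

#' Double-exponential tether survival fit
#'
#' Builds the empirical survival curve of tether lifetimes (censored
#' observations enter the at-risk set through a Kaplan--Meier estimate) and
#' fits the two-component exponential mixture
#' `S(t) = a exp(-t/tau1) + (1 - a) exp(-t/tau2)` by nonlinear least squares
#' on the curve. The characteristic half-life solves `S(t_half) = 1/2`
#' numerically.
#'
#' @param lifetimes observed lifetimes, s.
#' @param censored logical vector (TRUE = censored); default all observed.
#' @param min_uncensored minimum number of uncensored lifetimes (default 10).
#' @return object of class `survival_model`: list with `amplitude_1`,
#'   `tau_1`, `amplitude_2`, `tau_2`, `t_half`, `fit` (the nls object),
#'   `survival` (function of t).
#' @export
#' @examples
#' set.seed(1)
#' fit_survival(rexp(100, 1 / 20))$t_half  # ~ 20 log(2)
fit_survival <- function(lifetimes, censored = rep(FALSE, length(lifetimes)),
                         min_uncensored = 10) {
  stopifnot(length(lifetimes) == length(censored), all(lifetimes >= 0))
  if (sum(!censored) < min_uncensored) {
    stop("need at least ", min_uncensored, " uncensored lifetimes")
  }
  if (var(lifetimes[!censored]) == 0) {
    stop("degenerate data: all uncensored lifetimes identical")
  }
  km <- survival::survfit(survival::Surv(lifetimes, !censored) ~ 1)
  tt <- km$time[km$n.event > 0]
  ss <- km$surv[km$n.event > 0]
  m <- mean(lifetimes[!censored])
  start <- list(a = 0.6, tau1 = m / 2, tau2 = m * 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ss ~ a * exp(-tt / tau1) + (1 - a) * exp(-tt / tau2),
      start = start,
      lower = c(a = 0, tau1 = 1e-9, tau2 = 1e-9),
      upper = c(a = 1, tau1 = Inf, tau2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop("survival fit failed to converge: ",
                             conditionMessage(e))
  )
  cf <- coef(fit)
  # order components so tau_1 <= tau_2
  if (cf[["tau1"]] > cf[["tau2"]]) {
    cf <- c(a = 1 - cf[["a"]], tau1 = cf[["tau2"]], tau2 = cf[["tau1"]])
  }
  surv_fun <- function(t) {
    cf[["a"]] * exp(-t / cf[["tau1"]]) +
      (1 - cf[["a"]]) * exp(-t / cf[["tau2"]])
  }
  upper <- max(cf[["tau1"]], cf[["tau2"]]) * 100
  t_half <- uniroot(function(t) surv_fun(t) - 0.5, lower = 0, upper = upper,
                    tol = 1e-10)$root
  structure(
    list(amplitude_1 = cf[["a"]], tau_1 = cf[["tau1"]],
         amplitude_2 = 1 - cf[["a"]], tau_2 = cf[["tau2"]],
         t_half = t_half, fit = fit, survival = surv_fun,
         n = length(lifetimes), n_censored = sum(censored)),
    class = "survival_model"
  )
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf(
    "double-exponential survival: %.2f x exp(-t/%.3g s) + %.2f x exp(-t/%.3g s); t1/2 = %.3g s (n = %d, %d censored)\n",
    x$amplitude_1, x$tau_1, x$amplitude_2, x$tau_2, x$t_half, x$n,
    x$n_censored
  ))
  invisible(x)
}
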