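#' Unzipping curve
#'
#' Force versus number of base pairs unzipped, the working coordinate system
#' for roadblock analysis. Base-pair positions are 0-based offsets from the
#' first trunk base pair.
#'
#' @param bp_unzipped base pairs unzipped (series).
#' @param force pN (series).
#' @param full_length unzipping trunk length, bp.
#' @param breakage_position bp at which the tether broke, or NA.
#' @param aligned_offset alignment shift already applied, bp.
#' @return object of class `unzip_curve`.
#' @export
unzip_curve <- function(bp_unzipped, force, full_length,
                        breakage_position = NA_real_, aligned_offset = 0) {
  stopifnot(length(bp_unzipped) == length(force), full_length > 0)
  if (any(force <= 0, na.rm = TRUE)) stop("force must be positive")
  structure(
    list(bp_unzipped = bp_unzipped, force = force,
         full_length = full_length, breakage_position = breakage_position,
         aligned_offset = aligned_offset),
    class = "unzip_curve"
  )
}

#' @export
print.unzip_curve <- function(x, ...) {
  cat(sprintf(
    "unzip curve: %d points, 0..%d bp trunk, force %.1f..%.1f pN%s\n",
    length(x$force), x$full_length, min(x$force), max(x$force),
    if (!is.na(x$breakage_position)) {
      sprintf(", broke at %.0f bp", x$breakage_position)
    } else ""
  ))
  invisible(x)
}

#' Convert a force-extension trace to an unzipping curve
#'
#' Pointwise inversion of the series elasticity (dsDNA arms + 2 released
#' ssDNA nucleotides per opened base pair) via [unzip_bp_from_point()],
#' followed by boxcar smoothing of the base-pair series over the stated
#' window. Points where the inversion is infeasible (extension below the
#' arms-only extension) are flagged.
#'
#' @param trace an [fx_trace()] acquired during unzipping.
#' @param full_length trunk length, bp.
#' @param arm_bp total dsDNA arm length, bp.
#' @param arms,ss elasticity models.
#' @param smoothing_window s (default 0.025); 0 disables smoothing.
#' @param min_force points below this force are dropped (inversion
#'   ill-conditioned), pN.
#' @return an [unzip_curve()]; the fraction of flagged points is stored in
#'   the `flagged_fraction` field.
#' @export
to_unzip_curve <- function(trace, full_length, arm_bp = 6000,
                           arms = ds_dna_elasticity(),
                           ss = ss_dna_elasticity(),
                           smoothing_window = 0.025, min_force = 1) {
  keep <- trace$force_pN >= min_force
  f <- trace$force_pN[keep]
  x <- trace$extension_nm[keep]
  j <- unzip_bp_from_point(f, x, arm_bp, arms, ss)
  flagged <- attr(j, "flagged")
  rate <- attr(trace, "acquisition_rate")
  jj <- as.numeric(j)
  if (smoothing_window > 0) {
    w <- max(2L, as.integer(round(smoothing_window * rate)))
    jj <- .runmean(jj, w)
  }
  out <- unzip_curve(jj, f, full_length)
  out$flagged_fraction <- mean(flagged)
  out
}

# resample a curve onto an integer bp grid by averaging
.curve_on_grid <- function(curve, grid) {
  idx <- round(curve$bp_unzipped)
  ok <- idx >= min(grid) & idx <= max(grid)
  means <- tapply(curve$force[ok], idx[ok], mean)
  out <- rep(NA_real_, length(grid))
  out[match(as.integer(names(means)), grid)] <- means
  out
}

#' Align an unzipping curve to a baseline by cross-correlation
#'
#' Finds the integer base-pair offset that maximizes the cross-correlation
#' between the experimental force-versus-bp curve and a reference baseline
#' over protein-free regions, and shifts the curve by it. Regions elevated
#' above the baseline (putative protein contacts) are excluded from the
#' match.
#'
#' @param curve an [unzip_curve()].
#' @param baseline data.frame with `position` and `force_pN` (e.g. from
#'   [equilibrium_unzip_baseline()]), or another `unzip_curve`.
#' @param max_shift search radius, bp (default 200).
#' @param exclude_above exclude grid points where the (shifted) curve sits
#'   this far above the baseline, pN (default 2).
#' @param min_overlap minimum protein-free overlap required, bp (default
#'   200).
#' @return the curve with `aligned_offset` set and `bp_unzipped` shifted.
#' @export
align_to_baseline <- function(curve, baseline, max_shift = 200,
                              exclude_above = 2, min_overlap = 200) {
  if (inherits(baseline, "unzip_curve")) {
    grid <- seq(0L, as.integer(baseline$full_length))
    base_f <- .curve_on_grid(baseline, grid)
  } else {
    grid <- as.integer(round(baseline$position))
    base_f <- baseline$force_pN
  }
  if (max(base_f, na.rm = TRUE) - min(base_f, na.rm = TRUE) < 0.05) {
    stop("baseline is featureless; alignment is ambiguous")
  }
  shifts <- seq.int(-max_shift, max_shift)
  score <- rep(NA_real_, length(shifts))
  for (si in seq_along(shifts)) {
    sh <- shifts[si]
    shifted <- curve
    shifted$bp_unzipped <- curve$bp_unzipped + sh
    cf <- .curve_on_grid(shifted, grid)
    ok <- !is.na(cf) & !is.na(base_f) & (cf - base_f) < exclude_above
    if (sum(ok) < min_overlap) next
    a <- cf[ok] - mean(cf[ok])
    b <- base_f[ok] - mean(base_f[ok])
    score[si] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  if (all(is.na(score))) {
    stop("no shift gives at least ", min_overlap, " bp of protein-free overlap")
  }
  best <- shifts[which.max(score)]
  curve$bp_unzipped <- curve$bp_unzipped + best
  curve$aligned_offset <- curve$aligned_offset + best
  if (!is.na(curve$breakage_position)) {
    curve$breakage_position <- curve$breakage_position + best
  }
  curve
}

#' Interaction range of a bound roadblock
#'
#' Total DNA span (bp), before breakage, over which the unzipping force
#' exceeds the naked-DNA baseline by at least `threshold`. Consecutive
#' super-threshold runs are summed; sub-threshold gaps do not count; runs
#' shorter than `min_run` bp are ignored as noise.
#'
#' @param curve an aligned [unzip_curve()].
#' @param baseline data.frame with `position`, `force_pN`, or an
#'   `unzip_curve`.
#' @param threshold pN above baseline (default 2).
#' @param min_run minimum run length, bp (default 5).
#' @return total interaction range in bp.
#' @export
interaction_range <- function(curve, baseline, threshold = 2, min_run = 5) {
  if (missing(baseline) || is.null(baseline)) stop("baseline is required")
  if (inherits(baseline, "unzip_curve")) {
    grid <- seq(0L, as.integer(baseline$full_length))
    base_f <- .curve_on_grid(baseline, grid)
  } else {
    grid <- as.integer(round(baseline$position))
    base_f <- baseline$force_pN
  }
  cf <- .curve_on_grid(curve, grid)
  stop_at <- if (!is.na(curve$breakage_position)) curve$breakage_position else
    Inf
  above <- !is.na(cf) & !is.na(base_f) & (cf - base_f >= threshold) &
    grid < stop_at
  if (!any(above)) return(0)
  runs <- rle(above)
  lens <- runs$lengths[runs$values]
  sum(lens[lens >= min_run])
}

#' Maximum rupture force of an unzipping curve
#'
#' @param curve an [unzip_curve()] (already smoothed by [to_unzip_curve()]).
#' @return maximum force before breakage (or over the full curve), pN.
#' @export
max_rupture_force <- function(curve) {
  keep <- if (!is.na(curve$breakage_position)) {
    curve$bp_unzipped < curve$breakage_position
  } else rep(TRUE, length(curve$force))
  if (!any(keep)) keep <- rep(TRUE, length(curve$force))
  max(curve$force[keep])
}

#' Tether breakage probability with binomial error
#'
#' Fraction of unzipping tethers that broke before reaching the stated
#' fraction of the full trunk length, with the binomial standard error
#' `sqrt(p (1 - p) / n)`.
#'
#' @param curves list of [unzip_curve()] objects.
#' @param cutoff_fraction fraction of full length defining a break (default
#'   0.8).
#' @return list with `fraction`, `sem`, `n`, `k`.
#' @export
#' @examples
#' # 46 of 50 broke: p = 0.92, sem ~ 0.0384
breakage_probability <- function(curves, cutoff_fraction = 0.8) {
  stopifnot(length(curves) >= 1)
  broke <- vapply(curves, function(cu) {
    !is.na(cu$breakage_position) &&
      cu$breakage_position < cutoff_fraction * cu$full_length
  }, logical(1))
  n <- length(broke)
  k <- sum(broke)
  p <- k / n
  list(fraction = p, sem = sqrt(p * (1 - p) / n), n = n, k = k)
}
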