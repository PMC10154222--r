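#' Discretized worm-like-chain configuration
#'
#' Builds the coarse-grained chain used by the looping Monte Carlo: `n`
#' straight segments of equal length whose joints carry a harmonic bending
#' stiffness `g = Lp / b` (kT per joint). An optional rigid internal bend of
#' `bend_angle` degrees (tangent deviation from collinear; 150 deg is a
#' near-hairpin kink) is placed at the middle vertex and is excluded from
#' pivot moves, so the bend angle is preserved exactly.
#'
#' @param loop_bp total contour length of the loop in base pairs.
#' @param bend_angle internal bend in degrees (0 = unbent chain).
#' @param segment_bp discretization, bp per segment (default 5).
#' @param rise_per_bp nm per bp (default 0.338).
#' @return object of class `chain_config` with fields `vertices` ((n+1) x 3,
#'   nm), `segment_length` (nm), `n_segments`, `bend_vertex` (1-based vertex
#'   index or NA), `bend_angle`, `loop_bp`.
#' @export
#' @examples
#' chain_configuration(100, bend_angle = 150)
chain_configuration <- function(loop_bp, bend_angle = 0, segment_bp = 5,
                                rise_per_bp = .RISE_PER_BP) {
  stopifnot(loop_bp > 0, bend_angle >= 0, bend_angle < 180, segment_bp > 0)
  n <- max(2L, as.integer(round(loop_bp / segment_bp)))
  b <- loop_bp * rise_per_bp / n
  bend_vertex <- if (bend_angle > 0) as.integer(floor(n / 2)) + 1L else NA_integer_
  # straight chain along x; after the bend vertex the tangent is rotated by
  # bend_angle in the xy plane
  dirs <- matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)
  if (!is.na(bend_vertex)) {
    a <- bend_angle * pi / 180
    after <- seq.int(bend_vertex, n)   # segments following the bend joint
    dirs[after, ] <- matrix(rep(c(cos(a), sin(a), 0), length(after)),
                            ncol = 3, byrow = TRUE)
  }
  vertices <- rbind(c(0, 0, 0), apply(dirs * b, 2, cumsum))
  structure(
    list(vertices = vertices, segment_length = b, n_segments = n,
         bend_vertex = bend_vertex, bend_angle = bend_angle,
         loop_bp = loop_bp, rise_per_bp = rise_per_bp),
    class = "chain_config"
  )
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf(
    "WLC chain: %d bp, %d segments of %.3f nm%s, end-to-end %.2f nm\n",
    x$loop_bp, x$n_segments, x$segment_length,
    if (!is.na(x$bend_vertex)) {
      sprintf(", rigid %g deg bend at vertex %d", x$bend_angle, x$bend_vertex)
    } else "",
    end_to_end_distance(x)
  ))
  invisible(x)
}

#' End-to-end distance of a chain configuration
#' @param chain a `chain_config`.
#' @return nm.
#' @export
end_to_end_distance <- function(chain) {
  v <- chain$vertices
  sqrt(sum((v[nrow(v), ] - v[1, ])^2))
}

# validity check used by tests and after move sequences
validate_chain <- function(chain, tol = 1e-6) {
  v <- chain$vertices
  seg <- diff(v)
  len <- sqrt(rowSums(seg^2))
  if (max(abs(len - chain$segment_length)) / chain$segment_length > tol) {
    stop("segment lengths not preserved")
  }
  if (!is.na(chain$bend_vertex)) {
    i <- chain$bend_vertex
    a <- seg[i - 1, ]; b <- seg[i, ]
    ang <- acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
    if (abs(ang - chain$bend_angle) > 1e-4) {
      stop("bend angle not preserved")
    }
  }
  invisible(TRUE)
}

#' Bending energy of a chain configuration
#'
#' Harmonic-joint discretization of worm-like-chain bending: each interior
#' joint contributes `g (1 - cos theta)` in kT with `g = Lp / b`. The rigid
#' bend vertex (if any) is a constraint, not a thermal degree of freedom, and
#' contributes zero.
#'
#' @param chain a [chain_configuration()].
#' @param elasticity a [ds_dna_elasticity()] (persistence length sets g).
#' @return energy in kT units (>= 0; zero for a straight chain).
#' @export
bending_energy <- function(chain, elasticity = ds_dna_elasticity()) {
  validate_chain(chain)
  g <- elasticity$persistence_length / chain$segment_length
  bend0 <- if (is.na(chain$bend_vertex)) -1L else chain$bend_vertex - 1L
  .bend_energy_cpp(chain$vertices, bend0, g)
}

#' Umbrella bias spring constant
#'
#' Length- and bend-dependent stiffness schedule for the harmonic umbrella
#' restraint, `k = (1.682/25) exp(-0.008664 L) (55 - 0.2 alpha)` in pN nm per
#' squared bp of the bias coordinate.
#'
#' @param loop_bp total loop contour length, bp.
#' @param bend_angle internal bend, degrees (must be < 275 so k > 0).
#' @return k in pN nm / bp^2.
#' @export
#' @examples
#' bias_spring_constant(100, 150)
bias_spring_constant <- function(loop_bp, bend_angle = 0) {
  stopifnot(loop_bp > 0, bend_angle >= 0)
  if (any(bend_angle >= 275)) {
    stop("bend_angle >= 275 gives a non-positive spring constant")
  }
  (1.682 / 25) * exp(-0.008664 * loop_bp) * (55 - 0.2 * bend_angle)
}

#' Monte Carlo settings
#'
#' @param n_equil equilibration steps discarded before sampling (default 1e5).
#' @param n_prod production steps retained (default 1.5e6).
#' @param pivot_max_angle maximum pivot rotation, degrees (default 50).
#' @param temperature kelvin.
#' @param seed integer seed; every window derives its stream from it.
#' @param n_blocks contiguous production blocks for block-averaged errors.
#' @param bias_unit units of the bias coordinate r in U = k(r - r0)^2 / 2:
#'   `"bp"` (default, matching the stiffness units pN nm/bp^2) or `"nm"`.
#' @return object of class `mc_settings`.
#' @export
mc_settings <- function(n_equil = 1e5, n_prod = 1.5e6, pivot_max_angle = 50,
                        temperature = 296.15, seed = 1, n_blocks = 5,
                        bias_unit = c("bp", "nm")) {
  bias_unit <- match.arg(bias_unit)
  stopifnot(n_equil > 0, n_prod > 0,
            pivot_max_angle > 0, pivot_max_angle <= 180,
            temperature > 0, n_blocks >= 1)
  structure(
    list(n_equil = as.integer(n_equil), n_prod = as.integer(n_prod),
         pivot_max_angle = pivot_max_angle, temperature = temperature,
         seed = as.numeric(seed), n_blocks = as.integer(n_blocks),
         bias_unit = bias_unit),
    class = "mc_settings"
  )
}

#' Umbrella window
#'
#' @param r0 bias center, in the bias coordinate units of [mc_settings()]
#'   (bp by default; nm values are converted at run time).
#' @param k bias stiffness, pN nm per squared bias unit (0 = unbiased).
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(r0, k) {
  stopifnot(r0 >= 0, k >= 0)
  structure(list(r0 = r0, k = k, counts = NULL), class = "umbrella_window")
}

#' Single pivot proposal
#'
#' Proposes a pivot move: a random interior vertex of the non-bent chain is
#' chosen, and the shorter arm is rotated about a uniformly random axis
#' through that vertex by an angle uniform in `[-max_angle, max_angle]`. The
#' proposal is symmetric and preserves all segment lengths and the rigid bend
#' angle exactly. Randomness comes from R's RNG (seed with [set.seed()]).
#'
#' @param chain a [chain_configuration()].
#' @param max_angle maximum rotation, degrees (default 50).
#' @param angle optional fixed rotation angle in degrees (for testing).
#' @return a new `chain_config`.
#' @export
pivot_move <- function(chain, max_angle = 50, angle = NULL) {
  n <- chain$n_segments
  candidates <- setdiff(seq.int(2, n), chain$bend_vertex)
  pv <- if (length(candidates) == 1) candidates else sample(candidates, 1)
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  phi <- if (is.null(angle)) runif(1, -max_angle, max_angle) * pi / 180 else
    angle * pi / 180
  cphi <- cos(phi); sphi <- sin(phi)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- matrix(c(
    cphi + ux^2 * (1 - cphi), ux * uy * (1 - cphi) - uz * sphi,
    ux * uz * (1 - cphi) + uy * sphi,
    uy * ux * (1 - cphi) + uz * sphi, cphi + uy^2 * (1 - cphi),
    uy * uz * (1 - cphi) - ux * sphi,
    uz * ux * (1 - cphi) - uy * sphi, uz * uy * (1 - cphi) + ux * sphi,
    cphi + uz^2 * (1 - cphi)
  ), nrow = 3, byrow = TRUE)
  v <- chain$vertices
  nv <- nrow(v)
  idx <- if (nv - pv <= pv - 1) seq.int(pv + 1, nv) else seq.int(1, pv - 1)
  pivot <- v[pv, ]
  v[idx, ] <- sweep(sweep(v[idx, , drop = FALSE], 2, pivot) %*% t(R), 2,
                    pivot, `+`)
  chain$vertices <- v
  chain
}

#' Run umbrella-sampled Metropolis Monte Carlo in one window
#'
#' Equilibrates and samples the chain under its bending energy plus the
#' window's harmonic bias, using pivot moves and the Metropolis rule. The
#' first `n_equil` steps are discarded; the end-to-end distance of each of
#' the `n_prod` production states is histogrammed on a uniform grid.
#'
#' @param chain starting [chain_configuration()].
#' @param settings an [mc_settings()].
#' @param window an [umbrella_window()].
#' @param elasticity a [ds_dna_elasticity()].
#' @param binwidth histogram bin width, nm. Default
#'   `min(0.5, contour / 200)`.
#' @param seed seed for this run (default taken from settings).
#' @return the window with fields filled: `counts` (per-bin totals), `blocks`
#'   (bins x n_blocks), `breaks` (bin edges, nm), `n_samples`, `acceptance`,
#'   `mean_r`, `sd_r`, `max_energy_drift`, `final_chain`, `bias_unit_nm`.
#'   A warning is emitted if the production acceptance rate falls outside
#'   (0.01, 0.99).
#' @export
metropolis_run <- function(chain, settings = mc_settings(),
                           window = umbrella_window(0, 0),
                           elasticity = ds_dna_elasticity(),
                           binwidth = NULL, seed = settings$seed) {
  validate_chain(chain)
  contour <- chain$n_segments * chain$segment_length
  if (is.null(binwidth)) binwidth <- min(0.5, contour / 200)
  nbins <- as.integer(ceiling(contour / binwidth)) + 1L
  g <- elasticity$persistence_length / chain$segment_length
  bend0 <- if (is.na(chain$bend_vertex)) -1L else chain$bend_vertex - 1L
  unit_nm <- if (settings$bias_unit == "bp") chain$rise_per_bp else 1
  res <- .mc_umbrella_cpp(
    chain$vertices, bend0, g, window$k, window$r0, unit_nm,
    thermal_energy(settings$temperature), settings$n_equil, settings$n_prod,
    settings$pivot_max_angle, binwidth, nbins, settings$n_blocks,
    as.numeric(seed)
  )
  if (res$acceptance < 0.01 || res$acceptance > 0.99) {
    warning(sprintf(
      "window r0 = %g: production acceptance rate %.3f outside (0.01, 0.99)",
      window$r0, res$acceptance
    ))
  }
  window$blocks <- res$counts
  window$counts <- rowSums(res$counts)
  window$breaks <- seq(0, by = binwidth, length.out = nbins + 1L)
  window$n_samples <- sum(window$counts)
  window$acceptance <- res$acceptance
  window$mean_r <- res$mean_r
  window$sd_r <- res$sd_r
  window$max_energy_drift <- res$max_energy_drift
  window$bias_unit_nm <- unit_nm
  fin <- chain
  fin$vertices <- res$final_vertices
  window$final_chain <- fin
  window
}

#' Umbrella window schedule for a loop length
#'
#' Bias centers from near-contact (the capture distance) out to a fraction of
#' the reachable end-to-end range, plus one unbiased window that anchors the
#' bulk of the distribution. By default the number of biased windows adapts
#' to the bias stiffness: centers are spaced at about 1.25 times the thermal
#' fluctuation width `sqrt(kT / k)` so that adjacent histograms overlap.
#'
#' @param loop_bp loop length, bp.
#' @param n_windows total windows including the unbiased one; NULL (default)
#'   chooses automatically (at least 8, at most 64).
#' @param bend_angle degrees; sets the bias stiffness via
#'   [bias_spring_constant()].
#' @param r_capture_nm innermost center, nm (default 2).
#' @param r_max_frac outermost center as a fraction of the geometrically
#'   reachable maximum end-to-end distance (contour x cos(bend/2)); default
#'   0.7.
#' @param rise_per_bp nm per bp.
#' @param bias_unit `"bp"` or `"nm"` (must match the [mc_settings()] used).
#' @return list of [umbrella_window()] objects, innermost first, unbiased
#'   last.
#' @export
window_schedule <- function(loop_bp, n_windows = NULL, bend_angle = 0,
                            r_capture_nm = 2, r_max_frac = 0.7,
                            rise_per_bp = .RISE_PER_BP,
                            bias_unit = c("bp", "nm"),
                            temperature = 296.15) {
  bias_unit <- match.arg(bias_unit)
  stopifnot(loop_bp > 0)
  contour_nm <- loop_bp * rise_per_bp
  # a rigid mid-chain bend of a degrees caps r at contour * cos(a/2)
  r_reach <- contour_nm * cos(bend_angle * pi / 360)
  r_top <- max(r_max_frac * r_reach, 2 * r_capture_nm)
  k <- bias_spring_constant(loop_bp, bend_angle)
  kT <- thermal_energy(temperature)
  unit <- if (bias_unit == "bp") rise_per_bp else 1
  if (is.null(n_windows)) {
    # space centers at ~1.25 thermal widths so neighboring histograms overlap
    sigma_nm <- sqrt(kT / k) * unit
    n_windows <- ceiling((r_top - r_capture_nm) / (1.25 * sigma_nm)) + 2L
    n_windows <- min(max(n_windows, 12L), 64L)
  }
  stopifnot(n_windows >= 2)
  r0_nm <- seq(r_capture_nm, r_top, length.out = n_windows - 1)
  # floor the stiffness so each window can hold its center: without it, very
  # long loops get a bias too weak to ever sample the capture distance
  spacing_nm <- if (n_windows > 2) diff(r0_nm)[1] else r_top - r_capture_nm
  k_floor <- kT / ((spacing_nm / 1.25) / unit)^2
  wins <- lapply(r0_nm / unit, umbrella_window, k = max(k, k_floor))
  # tighten the innermost window (sigma ~ 1 nm) so the capture bin itself is
  # sampled densely rather than from the tail of a broad window
  k_inner <- kT / (max(r_capture_nm / 2, 1) / unit)^2
  wins[[1]]$k <- max(wins[[1]]$k, k_inner)
  c(wins, list(umbrella_window(0, 0)))
}

#' WHAM: unbias umbrella-window histograms
#'
#' Self-consistent weighted-histogram estimate of the unbiased end-to-end
#' distance density from a set of harmonically biased histograms sharing one
#' bin grid. Iterates the coupled equations for the per-window free-energy
#' offsets until the maximum change in any offset falls below `tol` (kT).
#'
#' @param windows list of filled windows from [metropolis_run()], or any list
#'   of lists with fields `counts`, `breaks`, `k`, `r0`, `bias_unit_nm`,
#'   `n_samples`.
#' @param temperature kelvin.
#' @param tol convergence tolerance on free-energy offsets, kT (default 1e-6).
#' @param max_iter iteration cap (default 1e5).
#' @return list with `r` (bin centers, nm), `P0` (density per nm, integrates
#'   to 1 over the sampled support), `free_energies` (kT, one per window),
#'   `n_iter`, `binwidth`.
#' @export
wham_unbias <- function(windows, temperature = 296.15, tol = 1e-6,
                        max_iter = 1e5) {
  stopifnot(length(windows) >= 1)
  breaks <- windows[[1]]$breaks
  for (w in windows) {
    if (!isTRUE(all.equal(w$breaks, breaks))) {
      stop("all windows must share one histogram grid")
    }
  }
  kT <- thermal_energy(temperature)
  r_mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  binwidth <- diff(breaks)[1]
  counts <- vapply(windows, function(w) as.numeric(w$counts),
                   numeric(length(r_mid)))
  N <- colSums(counts)
  if (any(N == 0)) stop("window with no samples")

  # check that occupied supports form one connected component
  occ <- counts > 0
  if (length(windows) > 1) {
    adj <- crossprod(occ) > 0
    comp <- rep(0L, ncol(adj)); comp[1] <- 1L
    repeat {
      reach <- which(rowSums(adj[, comp == 1L, drop = FALSE]) > 0 & comp == 0L)
      if (!length(reach)) break
      comp[reach] <- 1L
    }
    if (any(comp == 0L)) {
      stop(sprintf(
        "disjoint window supports: windows {%s} share no bins with window 1's component",
        paste(which(comp == 0L), collapse = ", ")
      ))
    }
  }

  # bias weights c_im = exp(-U_i(r_m))
  U <- vapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    if (w$k <= 0) rep(0, length(r_mid)) else {
      0.5 * w$k * (r_mid / w$bias_unit_nm - w$r0)^2 / kT
    }
  }, numeric(length(r_mid)))
  cmat <- exp(-U)  # bins x windows

  num <- rowSums(counts)
  f <- rep(0, length(windows))  # -log of window partition ratios, kT
  for (it in seq_len(max_iter)) {
    denom <- as.vector(cmat %*% (N * exp(f)))
    p <- ifelse(denom > 0, num / denom, 0)
    p <- p / sum(p)
    f_new <- -log(pmax(as.vector(crossprod(cmat, p)), .Machine$double.xmin))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      return(list(r = r_mid, P0 = p / binwidth, free_energies = f,
                  n_iter = it, binwidth = binwidth))
    }
  }
  stop(sprintf(
    "WHAM failed to converge in %d iterations (last offset change %.3g kT)",
    as.integer(max_iter), delta
  ))
}

#' J-factor from an unbiased end-to-end density
#'
#' Converts the radial end-to-end density into the Jacobson--Stockmayer
#' looping J-factor at the capture distance, `J(r) = P0(r) / (4 pi r^2)`,
#' expressed in nM through the Avogadro constant (1 molecule per nm^3 =
#' 1.66054e9 nM).
#'
#' @param P0 result of [wham_unbias()] (a list with `r` and `P0`), or a
#'   numeric density vector with `r` supplied separately.
#' @param r bin centers in nm (when `P0` is a bare vector).
#' @param r_capture capture distance, nm (default 2).
#' @return J in nM.
#' @export
#' @examples
#' # one end uniform in a sphere of radius R: J = 1 / (N_A V)
#' R <- 100
#' r <- seq(0.25, R, by = 0.5)
#' j_factor_from_p0(3 * r^2 / R^3, r = r, r_capture = 2)
j_factor_from_p0 <- function(P0, r = NULL, r_capture = 2) {
  if (is.list(P0)) {
    r <- P0$r
    P0 <- P0$P0
  }
  stopifnot(length(P0) == length(r), all(P0 >= -1e-12))
  half <- diff(r)[1] / 2
  if (r_capture < min(r) - half || r_capture > max(r) + half) {
    stop("r_capture outside the sampled support")
  }
  i <- which.min(abs(r - r_capture))
  P0[i] / (4 * pi * r[i]^2) * .NM3_TO_NANOMOLAR
}

#' J-factor versus loop length
#'
#' For each loop length, runs the full umbrella-sampling pipeline: window
#' schedule, pivot Monte Carlo per window (warm-started from the neighboring
#' window, outermost first), WHAM unbiasing, and the J-factor at the capture
#' distance. Standard errors come from block averaging: WHAM is repeated on
#' each of `settings$n_blocks` contiguous production blocks.
#'
#' @param loop_bp vector of loop lengths, bp.
#' @param bend_angle internal bend, degrees (0 = unbent DNA).
#' @param settings an [mc_settings()]; the seed determines every window
#'   stream, so equal seeds give bit-identical profiles.
#' @param elasticity a [ds_dna_elasticity()].
#' @param n_windows umbrella windows per length; NULL (default) adapts to
#'   the bias stiffness, see [window_schedule()].
#' @param r_capture capture distance, nm (default 2).
#' @param segment_bp discretization, bp per segment.
#' @param r_max_frac outermost bias center as a fraction of contour.
#' @return object of class `jfactor_profile_set`: a list of per-length
#'   profiles (`loop_bp`, `J_nM`, `J_se`, `r`, `P0`, window diagnostics) plus
#'   a `summary` data.frame (columns `L_bp`, `J_nM`, `J_se`).
#' @export
j_factor_curve <- function(loop_bp, bend_angle = 0, settings = mc_settings(),
                           elasticity = ds_dna_elasticity(), n_windows = NULL,
                           r_capture = 2, segment_bp = 5, r_max_frac = 0.7) {
  profiles <- lapply(seq_along(loop_bp), function(iL) {
    L <- loop_bp[iL]
    chain <- chain_configuration(L, bend_angle, segment_bp,
                                 elasticity$rise_per_bp)
    if (chain$n_segments < 4) stop("loop too short after discretization")
    wins <- window_schedule(L, n_windows, bend_angle, r_capture, r_max_frac,
                            elasticity$rise_per_bp, settings$bias_unit,
                            settings$temperature)
    nw <- length(wins)
    contour <- chain$n_segments * chain$segment_length
    binwidth <- min(0.5, contour / 200)
    # run outermost biased window first (closest to the stretched start),
    # then walk inward, warm-starting each window from the previous one;
    # the unbiased window starts from the initial configuration
    order_idx <- c(rev(seq_len(nw - 1)), nw)
    filled <- vector("list", nw)
    start <- chain
    for (iw in order_idx) {
      w <- wins[[iw]]
      st <- if (iw == nw) chain else start
      seed_iw <- settings$seed * 1e4 + iL * 1000 + iw
      filled[[iw]] <- metropolis_run(st, settings, w, elasticity,
                                     binwidth = binwidth, seed = seed_iw)
      if (iw != nw) start <- filled[[iw]]$final_chain
    }
    wh <- wham_unbias(filled, settings$temperature)
    J <- j_factor_from_p0(wh, r_capture = r_capture)
    # block-averaged error
    Jb <- vapply(seq_len(settings$n_blocks), function(b) {
      wb <- lapply(filled, function(w) {
        w$counts <- w$blocks[, b]
        w$n_samples <- sum(w$counts)
        w
      })
      ok <- vapply(wb, function(w) w$n_samples > 0, logical(1))
      j_factor_from_p0(wham_unbias(wb[ok], settings$temperature),
                       r_capture = r_capture)
    }, numeric(1))
    J_se <- sd(Jb) / sqrt(settings$n_blocks)
    structure(
      list(loop_bp = L, bend_angle = bend_angle, J_nM = J, J_se = J_se,
           J_blocks = Jb, r = wh$r, P0 = wh$P0, r_capture = r_capture,
           windows = lapply(filled, function(w) {
             list(r0 = w$r0, k = w$k, acceptance = w$acceptance,
                  mean_r = w$mean_r, sd_r = w$sd_r,
                  max_energy_drift = w$max_energy_drift)
           })),
      class = "jfactor_profile"
    )
  })
  structure(
    list(profiles = profiles,
         summary = data.frame(
           L_bp = loop_bp,
           J_nM = vapply(profiles, `[[`, numeric(1), "J_nM"),
           J_se = vapply(profiles, `[[`, numeric(1), "J_se")
         ),
         bend_angle = bend_angle, settings = settings),
    class = "jfactor_profile_set"
  )
}

#' @export
print.jfactor_profile_set <- function(x, ...) {
  cat(sprintf("J-factor curve (bend %g deg):\n", x$bend_angle))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-population fit of a loop-size histogram
#'
#' Scales the unbent and bent J-factor curves by non-negative least squares
#' to match an observed loop-size histogram:
#' `counts ~ a J_unbent(L) + b J_bent(L)`, `a, b >= 0`.
#'
#' @param profile_unbent,profile_bent `jfactor_profile_set` objects (or data
#'   frames with columns `L_bp`, `J_nM`).
#' @param observed data.frame with columns `loop_bp` (bin centers) and
#'   `count`.
#' @return list with `scale_unbent`, `scale_bent`, `composite` (fitted counts
#'   at the bin centers), `residual` (RSS).
#' @export
predict_loop_size_distribution <- function(profile_unbent, profile_bent,
                                           observed) {
  as_tab <- function(p) if (inherits(p, "jfactor_profile_set")) p$summary else p
  tu <- as_tab(profile_unbent)
  tb <- as_tab(profile_bent)
  stopifnot(all(c("loop_bp", "count") %in% names(observed)))
  if (all(observed$count == 0)) stop("observed histogram is all zero")
  L <- observed$loop_bp
  lo <- max(min(tu$L_bp), min(tb$L_bp))
  hi <- min(max(tu$L_bp), max(tb$L_bp))
  keep <- L >= lo & L <= hi
  if (!any(keep)) stop("histogram support does not overlap the profiles")
  ju <- approx(tu$L_bp, tu$J_nM, xout = L[keep])$y
  jb <- approx(tb$L_bp, tb$J_nM, xout = L[keep])$y
  y <- observed$count[keep]
  # two-variable non-negative least squares: try interior, then both edges
  fit2 <- function() {
    A <- cbind(ju, jb)
    ab <- tryCatch(solve(crossprod(A), crossprod(A, y)),
                   error = function(e) c(-1, -1))
    c(ab)
  }
  cand <- list(fit2(),
               c(max(0, sum(ju * y) / sum(ju^2)), 0),
               c(0, max(0, sum(jb * y) / sum(jb^2))))
  cand <- Filter(function(v) all(v >= 0), cand)
  rss <- vapply(cand, function(v) sum((y - v[1] * ju - v[2] * jb)^2),
                numeric(1))
  best <- cand[[which.min(rss)]]
  list(scale_unbent = best[1], scale_bent = best[2],
       composite = data.frame(loop_bp = L[keep],
                              fitted = best[1] * ju + best[2] * jb),
       residual = min(rss))
}
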