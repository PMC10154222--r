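#' dsDNA elasticity parameters
#'
#' Parameter set for the modified Marko--Siggia worm-like chain used to model
#' double-stranded DNA under tension. The "modified" model adds an enthalpic
#' stretch modulus \eqn{K} to the inextensible worm-like chain: the force
#' depends on the effective normalized extension \eqn{l = x/L_0 - F/K},
#' \deqn{F = (k_BT/L_p)\left[\frac{1}{4(1-l)^2} - \frac14 + l\right].}
#'
#' @param persistence_length persistence length in nm (default 45).
#' @param stretch_modulus enthalpic stretch modulus in pN (default 1200; set
#'   `Inf` for the inextensible limit).
#' @param rise_per_bp helical rise in nm per bp (0.338).
#' @param temperature temperature in kelvin (default 296.15, i.e. 23 C).
#' @return object of class `ds_elasticity`.
#' @export
#' @examples
#' ds_dna_elasticity()
ds_dna_elasticity <- function(persistence_length = 45,
                              stretch_modulus = 1200,
                              rise_per_bp = 0.338,
                              temperature = 296.15) {
  stopifnot(
    is.numeric(persistence_length), persistence_length > 0,
    is.numeric(stretch_modulus), stretch_modulus > 0,
    is.numeric(rise_per_bp), rise_per_bp > 0,
    is.numeric(temperature), temperature > 0
  )
  structure(
    list(
      persistence_length = persistence_length,
      stretch_modulus = stretch_modulus,
      rise_per_bp = rise_per_bp,
      temperature = temperature,
      kT = thermal_energy(temperature)
    ),
    class = "ds_elasticity"
  )
}

#' @export
print.ds_elasticity <- function(x, ...) {
  cat(sprintf(
    "dsDNA worm-like chain: Lp = %g nm, K = %g pN, rise = %g nm/bp, T = %g K\n",
    x$persistence_length, x$stretch_modulus, x$rise_per_bp, x$temperature
  ))
  invisible(x)
}

#' ssDNA elasticity parameters
#'
#' Extensible freely-jointed chain for single-stranded DNA: the mean extension
#' per nucleotide at force \eqn{F} is
#' \deqn{x(F) = c \left[\coth(Fb/k_BT) - k_BT/(Fb)\right](1 + F/S)}
#' with Kuhn length \eqn{b}, contour per nucleotide \eqn{c} and stretch
#' modulus \eqn{S}. Defaults follow the classic single-molecule ssDNA
#' characterization (b = 1.5 nm, c = 0.56 nm/nt, S = 800 pN).
#'
#' @param contour_per_nt contour length per nucleotide, nm.
#' @param kuhn_length Kuhn segment length, nm.
#' @param stretch_modulus ssDNA stretch modulus, pN.
#' @param temperature kelvin.
#' @return object of class `ss_elasticity`.
#' @export
ss_dna_elasticity <- function(contour_per_nt = 0.56,
                              kuhn_length = 1.5,
                              stretch_modulus = 800,
                              temperature = 296.15) {
  stopifnot(
    contour_per_nt > 0, kuhn_length > 0, stretch_modulus > 0, temperature > 0
  )
  structure(
    list(
      contour_per_nt = contour_per_nt,
      kuhn_length = kuhn_length,
      stretch_modulus = stretch_modulus,
      temperature = temperature,
      kT = thermal_energy(temperature)
    ),
    class = "ss_elasticity"
  )
}

#' @export
print.ss_elasticity <- function(x, ...) {
  cat(sprintf(
    "ssDNA extensible FJC: c = %g nm/nt, b = %g nm, S = %g pN, T = %g K\n",
    x$contour_per_nt, x$kuhn_length, x$stretch_modulus, x$temperature
  ))
  invisible(x)
}

# inextensible Marko-Siggia force at fractional extension l in [0, 1)
.ms_force <- function(l, elasticity) {
  elasticity$kT / elasticity$persistence_length *
    (1 / (4 * (1 - l)^2) - 0.25 + l)
}

# inverse of the inextensible Marko-Siggia relation (vectorized, monotone)
.ms_fraction_at_force <- function(force, elasticity) {
  vapply(force, function(f) {
    if (f <= 0) return(0)
    # force diverges as l -> 1: bracket is always valid
    uniroot(function(l) .ms_force(l, elasticity) - f,
            lower = 0, upper = 1 - 1e-12, tol = 1e-12)$root
  }, numeric(1))
}

#' Worm-like-chain force at a normalized extension
#'
#' Solves the modified Marko--Siggia relation for the tension on dsDNA at a
#' given normalized extension `x_norm = x / L0`. With a finite stretch
#' modulus the relation is implicit (the enthalpic term enters through the
#' effective coordinate `x_norm - F/K`) and is solved numerically; the result
#' is strictly increasing in `x_norm`.
#'
#' @param x_norm extension divided by contour length (dimensionless, >= 0;
#'   values above 1 are admissible for a finite stretch modulus).
#' @param elasticity a [ds_dna_elasticity()] object.
#' @return force in pN (vectorized over `x_norm`).
#' @export
#' @examples
#' wlc_force_at_extension(0.5, ds_dna_elasticity(stretch_modulus = Inf))
wlc_force_at_extension <- function(x_norm, elasticity = ds_dna_elasticity()) {
  if (!all(is.finite(x_norm))) {
    stop("x_norm must be finite")
  }
  if (any(x_norm < 0)) {
    stop("x_norm must be non-negative")
  }
  K <- elasticity$stretch_modulus
  vapply(x_norm, function(xn) {
    if (xn == 0) return(0)
    if (is.infinite(K)) {
      if (xn >= 1) stop("x_norm >= 1 requires a finite stretch modulus")
      return(.ms_force(xn, elasticity))
    }
    # F - MS(xn - F/K) = 0 is monotone increasing in F; bracket then root-find
    g <- function(f) f - .ms_force(pmin(pmax(xn - f / K, 0), 1 - 1e-12),
                                   elasticity)
    upper <- max(10, elasticity$kT / elasticity$persistence_length * 10)
    while (g(upper) < 0) {
      upper <- upper * 2
      if (upper > 1e7) stop("force bracketing failed to converge")
    }
    uniroot(g, lower = 0, upper = upper, tol = 1e-10)$root
  }, numeric(1))
}

#' Fractional dsDNA extension at a given force
#'
#' Inverse of [wlc_force_at_extension()]: the expected extension per unit
#' contour length at tension `force`.
#'
#' @param force tension in pN (vectorized).
#' @param elasticity a [ds_dna_elasticity()] object.
#' @return dimensionless x/L0.
#' @export
wlc_extension_at_force <- function(force, elasticity = ds_dna_elasticity()) {
  stopifnot(all(is.finite(force)), all(force >= 0))
  l <- .ms_fraction_at_force(force, elasticity)
  if (is.infinite(elasticity$stretch_modulus)) l else {
    l + force / elasticity$stretch_modulus
  }
}

#' ssDNA extension per nucleotide at force
#'
#' @param force pN (vectorized).
#' @param ss an [ss_dna_elasticity()] object.
#' @return extension per nucleotide, nm.
#' @export
ssdna_extension_per_nt <- function(force, ss = ss_dna_elasticity()) {
  stopifnot(all(is.finite(force)), all(force >= 0))
  a <- force * ss$kuhn_length / ss$kT
  langevin <- ifelse(a < 1e-6, a / 3, 1 / tanh(a) - 1 / a)
  ss$contour_per_nt * langevin * (1 + force / ss$stretch_modulus)
}

# Gibbs stretching free energy of one ssDNA nucleotide at fixed force:
# integral_0^F x(F') dF', in pN nm. Closed form for the FJC part, quadratic
# term for the enthalpic correction (integral of c * L(a) * F/S dF done
# numerically would be overkill; use exact FJC log term + numeric remainder).
.ssdna_stretch_energy <- function(force, ss = ss_dna_elasticity()) {
  vapply(force, function(f) {
    if (f <= 0) return(0)
    a <- f * ss$kuhn_length / ss$kT
    fjc <- ss$contour_per_nt * ss$kT / ss$kuhn_length * (log(sinh(a) / a))
    # enthalpic remainder integral c*L(a')*F'/S dF' via fine quadrature
    grid <- seq(0, f, length.out = 64)
    ag <- grid * ss$kuhn_length / ss$kT
    lg <- ifelse(ag < 1e-6, ag / 3, 1 / tanh(ag) - 1 / ag)
    enth <- pracma::trapz(grid, ss$contour_per_nt * lg * grid /
                            ss$stretch_modulus)
    fjc + enth
  }, numeric(1))
}

#' Contour length from a (force, extension) point
#'
#' Given a measured tension and end-to-end extension, returns the dsDNA
#' contour length in base pairs implied by the modified Marko--Siggia model
#' (extension divided by the model's fractional extension at that force,
#' converted through the helical rise). Below the low-force cutoff the
#' inversion is ill-conditioned and the result carries a `reliable = FALSE`
#' flag rather than being silently returned.
#'
#' @param force pN (vectorized).
#' @param extension nm (vectorized, recycled against force).
#' @param elasticity a [ds_dna_elasticity()] object.
#' @param force_cutoff low-force reliability cutoff, pN (default 0.25).
#' @return numeric vector of contour lengths in bp with attribute
#'   `reliable` (logical vector).
#' @export
#' @examples
#' el <- ds_dna_elasticity()
#' x <- 12688 * 0.338 * wlc_extension_at_force(5, el)
#' contour_length_from_point(5, x, el)
contour_length_from_point <- function(force, extension,
                                      elasticity = ds_dna_elasticity(),
                                      force_cutoff = 0.25) {
  stopifnot(all(is.finite(force)), all(is.finite(extension)))
  if (any(force <= 0)) stop("force must be positive")
  n <- max(length(force), length(extension))
  force <- rep_len(force, n)
  extension <- rep_len(extension, n)
  frac <- wlc_extension_at_force(force, elasticity)
  bp <- extension / (frac * elasticity$rise_per_bp)
  structure(bp, reliable = force >= force_cutoff)
}

#' Base pairs unzipped from a (force, extension) point
#'
#' Solves the series elasticity of an unzipping construct: total extension =
#' dsDNA-arm extension + 2 j ssDNA nucleotides, for the number of opened base
#' pairs j. Points whose extension falls below the arms-only extension return
#' j = 0 with a `flagged` attribute.
#'
#' @param force pN (vectorized).
#' @param extension nm.
#' @param arm_bp total dsDNA arm length in bp.
#' @param arms [ds_dna_elasticity()] for the arms.
#' @param ss [ss_dna_elasticity()] for the released strands.
#' @return numeric vector of base pairs unzipped, attribute `flagged`.
#' @export
unzip_bp_from_point <- function(force, extension, arm_bp = 6000,
                                arms = ds_dna_elasticity(),
                                ss = ss_dna_elasticity()) {
  stopifnot(all(is.finite(force)), all(is.finite(extension)), arm_bp >= 0)
  if (any(force <= 0)) stop("force must be positive")
  n <- max(length(force), length(extension))
  force <- rep_len(force, n)
  extension <- rep_len(extension, n)
  x_arms <- arm_bp * arms$rise_per_bp * wlc_extension_at_force(force, arms)
  x_nt <- ssdna_extension_per_nt(force, ss)
  j <- (extension - x_arms) / (2 * x_nt)
  flagged <- j < 0
  j[flagged] <- 0
  structure(j, flagged = flagged)
}

#' Equilibrium unzipping force baseline for a DNA sequence
#'
#' For each fork position j the equilibrium unzipping force balances the
#' nearest-neighbor base-pairing free energy of opening base pair j against
#' the work gained by releasing two single-stranded nucleotides held at that
#' force: \eqn{\Delta G_j = 2 \int_0^F x_{ss}(F')\,dF'}. The resulting
#' force-versus-position curve is the naked-DNA unzipping baseline; for a
#' random 50% GC sequence it sits near 15 pN.
#'
#' @param sequence DNA sequence, a single string over A/C/G/T.
#' @param ss [ss_dna_elasticity()] for the released strands.
#' @param nn_params nearest-neighbor parameter table, see [nn_parameters()].
#' @param fork_window sliding window (bp) over which per-bp opening free
#'   energies are averaged before force balancing (default 30). The
#'   unzipping fork fluctuates over many base pairs at equilibrium, so the
#'   measured force responds to the locally averaged pairing energy rather
#'   than to single-bp values; 1 disables averaging.
#' @return data.frame with columns `position` (bp index, 0-based offset from
#'   the first trunk base pair) and `force_pN`.
#' @export
#' @examples
#' seqc <- random_dna_sequence(500, gc = 0.5, seed = 1)
#' mean(equilibrium_unzip_baseline(seqc)$force_pN)
equilibrium_unzip_baseline <- function(sequence,
                                       ss = ss_dna_elasticity(),
                                       nn_params = nn_parameters(),
                                       fork_window = 30) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2) stop("sequence must contain at least 2 bases")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("sequence contains characters outside {A,C,G,T}")
  }
  steps <- paste0(bases[-length(bases)], bases[-1])
  dg_kcal <- nn_params$dG[steps]   # negative, kcal/mol, at T and salt
  if (anyNA(dg_kcal)) stop("unknown dinucleotide step")
  # opening cost in pN nm per bp
  rt_kcal <- 8.314462618 * ss$temperature / 4184  # kcal/mol per kT
  open_cost <- -dg_kcal / rt_kcal * ss$kT
  if (fork_window > 1) {
    open_cost <- .runmean(open_cost, as.integer(fork_window))
  }
  # solve 2 * g_ss(F) = cost by inverting the monotone work function once
  fgrid <- seq(0.05, 200, length.out = 600)
  cost_grid <- 2 * .ssdna_stretch_energy(fgrid, ss)
  force <- approx(cost_grid, fgrid, xout = open_cost, rule = 2)$y
  data.frame(position = seq_along(steps) - 1L, force_pN = force)
}

#' Nearest-neighbor base-pairing free energies
#'
#' Unified nearest-neighbor thermodynamic parameters (dH in kcal/mol, dS in
#' cal/mol/K per stack) with an entropic salt correction using an effective
#' monovalent concentration (monovalent plus 3.3 sqrt(Mg)). Free energies are
#' evaluated at the requested temperature.
#'
#' @param temperature kelvin.
#' @param monovalent monovalent cation concentration, M (default 0.1).
#' @param magnesium Mg2+ concentration, M (default 0.003).
#' @param energy_scale multiplier applied to all pairing free energies
#'   (1 = published values); exposed for sensitivity analyses.
#' @return list with named vectors `dH`, `dS`, `dG` (indexed by the 16
#'   dinucleotide steps, 5'->3' on the opened strand) and the settings used.
#' @export
nn_parameters <- function(temperature = 296.15, monovalent = 0.1,
                          magnesium = 0.003, energy_scale = 1) {
  stopifnot(temperature > 0, monovalent > 0, magnesium >= 0, energy_scale > 0)
  # unified NN set: dH kcal/mol, dS cal/(mol K); 10 unique duplex stacks
  dH10 <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS10 <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  key <- vapply(steps, function(s) {
    rc <- paste0(comp[substr(s, 2, 2)], comp[substr(s, 1, 1)])
    if (s %in% names(dH10)) s else rc
  }, character(1))
  dH <- setNames(dH10[key], steps)
  dS <- setNames(dS10[key], steps)
  na_eff <- monovalent + 3.3 * sqrt(magnesium)
  dS_corr <- dS + 0.368 * log(na_eff)
  dG <- (dH - temperature * dS_corr / 1000) * energy_scale
  list(dH = dH, dS = dS_corr, dG = dG, temperature = temperature,
       na_eff = na_eff, energy_scale = energy_scale)
}

#' Random DNA sequence with a target GC content
#'
#' @param n length in bases.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @return a single character string.
#' @export
random_dna_sequence <- function(n, gc = 0.5, seed = NULL) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
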