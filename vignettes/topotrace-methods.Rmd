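---
title: "Models and methods behind topotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind topotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

topotrace implements the computational apparatus of single-molecule
topoisomerase II experiments: a worm-like-chain (WLC) looping simulator and
the trace-analysis pipelines for DNA stretching, unzipping, and twisting
assays. This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic-data tests demonstrate.

# Polymer elasticity

## dsDNA: the modified Marko–Siggia chain

Double-stranded DNA under tension is modeled as an extensible worm-like
chain. The force at fractional extension $l$ obeys

$$F = \frac{k_BT}{L_p}\left[\frac{1}{4(1-l)^2} - \frac14 + l\right],
\qquad l = \frac{x}{L_0} - \frac{F}{K},$$

with persistence length $L_p = 45$ nm, helical rise 0.338 nm/bp, and
temperature 23 °C ($k_BT \approx 4.09$ pN·nm). Two "modified" variants
circulate in the literature, differing in where the enthalpic term enters;
we use the substitution form above (the stretch correction shifts the
effective fractional extension), with the inextensible limit available by
setting `stretch_modulus = Inf`. The stretch modulus itself is not
determined by the assays modeled here; the default $K = 1200$ pN is typical
for dsDNA in near-physiological buffers and is configurable.

Given a measured $(F, x)$ pair the relation is inverted for the contour
length $L_0$, reported in base pairs. Below 0.25 pN the inversion becomes
ill-conditioned (the extension depends only weakly on contour length), so
`contour_length_from_point()` flags such points rather than returning them
silently; the DNA-compaction observable is measured at 0.5 pN, comfortably
above the cutoff.

## ssDNA: extensible freely-jointed chain

Released single strands follow an extensible freely-jointed chain,
$x(F) = c\,[\coth(Fb/k_BT) - k_BT/Fb]\,(1 + F/S)$ per nucleotide, with Kuhn
length $b = 1.5$ nm, contour $c = 0.56$ nm/nt and stretch modulus
$S = 800$ pN — the classic parameterization from single-molecule ssDNA
stretching. The number of base pairs unzipped follows from the series
construction: total extension = dsDNA arms + $2j$ ssDNA nucleotides.

## Equilibrium unzipping baseline

At a fixed force $F$, opening base pair $j$ trades its nearest-neighbor
pairing free energy $\Delta G_j$ against the stretching free energy of the
two released nucleotides, $2\int_0^F x_{ss}(F')\,dF'$. Solving this balance
per position gives the deterministic naked-DNA force baseline. We use the
unified nearest-neighbor parameter set ($\Delta H$, $\Delta S$ per stack)
evaluated at 23 °C with an entropic salt correction using the effective
monovalent concentration $[\mathrm{Mon}] + 3.3\sqrt{[\mathrm{Mg}]}$
(defaults 100 mM monovalent + 3 mM Mg²⁺, matching the assay buffer scale).
Because the unzipping fork fluctuates over tens of base pairs at
equilibrium, per-bp energies are averaged over a sliding 30 bp window before
force balancing; single-bp resolution is not physical in this measurement
and the window only suppresses sequence-level jaggedness (the mean is
unchanged). For a random 50% GC sequence the baseline averages ~15–16.5 pN,
consistent with the canonical ~15 pN naked-DNA unzipping plateau.

# The looping Monte Carlo

## Discretization and the protein-induced bend

The loop is a chain of $n$ rigid segments of $b \approx 5$ bp (1.69 nm),
with harmonic joint stiffness $g = L_p/b \approx 26.6\,k_BT$; 5 bp is fine
enough to resolve ~100 bp loops while keeping desk-scale runtimes. A bound
protein that bends DNA is represented as a rigid kink at the middle vertex:
the bend angle $\alpha$ is the *tangent deviation from collinear*, so
$\alpha = 150^\circ$ is a near-hairpin kink (the opposite convention —
included angle — is defensible; with it, 150° would mean a mild 30°
deviation, which cannot produce short-loop enhancement). The kink vertex is
excluded from pivot selection, so its angle is preserved exactly and
contributes no thermal energy.

## Sampling

Moves are pivot rotations: a random interior vertex of the non-bent chain,
a uniformly random axis through it, a rotation angle uniform in
[−50°, 50°]; the shorter arm is rotated (both arms carry a chain end, so the
end-to-end distance changes either way, and the proposal stays symmetric).
Acceptance is Metropolis on bending energy plus the umbrella bias
$U = \tfrac12 k (r - r_0)^2$. Energy is tracked incrementally (only the
pivot-vertex joint changes) and recomputed from scratch every $10^4$ steps;
the tracked-vs-recomputed drift is reported and stays below $10^{-6}\,k_BT$.
Each run discards $10^5$ equilibration steps and samples $1.5 \times 10^6$
production steps by default. All randomness flows through a dedicated
64-bit generator seeded per window, so equal seeds give bit-identical
histograms.

## Bias coordinate, spring constant and the window ladder

The printed stiffness schedule
$k = (1.682/25)\,e^{-0.008664 L}(55 - 0.2\alpha)$ carries units of
pN·nm/bp², so the bias coordinate is taken in bp equivalents
($r_\mathrm{nm}/0.338$); an nm interpretation is available as a
configuration switch. Window centers run linearly from the 2 nm capture
distance to 70% of the geometrically reachable end-to-end maximum
($\mathrm{contour}\times\cos(\alpha/2)$ for a mid-chain kink), plus one
unbiased window that anchors the bulk of the distribution.

Two numerical guards adapt the ladder to the stiffness schedule. First, the
number of windows is chosen so neighboring centers sit ~1.25 thermal widths
$\sigma = \sqrt{k_BT/k}$ apart (between 8 and 64 windows): at intermediate
unbent lengths the schedule's $k$ is stiff enough that a fixed 8–10 window
ladder would leave disjoint histogram supports. Second, because the
schedule decays exponentially in $L$, at long loop lengths $k$ becomes too
weak for a window to hold its center at all (at $L \sim 1300$ bp the
thermal width exceeds 300 bp), so each window's stiffness is floored at
$k_BT/(\Delta/1.25)^2$ for ladder spacing $\Delta$, and the innermost
window is tightened to $\sigma \approx 1$ nm so the capture bin itself is
densely sampled. Wherever the printed schedule is at least as stiff — in
particular for bent DNA at short lengths — it is used verbatim.

## WHAM and the J-factor

Windows share one histogram grid with bin width
$\min(0.5\ \mathrm{nm}, \mathrm{contour}/200)$. The weighted-histogram
equations are iterated until every window free-energy offset changes by
less than $10^{-6}\,k_BT$ (cap $10^5$ iterations, with an explicit residual
in the error on non-convergence); disjoint window supports are detected via
the bin-sharing graph and reported by window index. The unbiased $P^0(r)$
is normalized over the sampled support, and
$J(r) = P^0(r)/(4\pi r^2)$, read in the bin containing $r = 2$ nm, is
converted to nM with the Avogadro constant
(1 molecule/nm³ = $1.66054\times10^9$ nM). Standard errors come from block
averaging: production is split into 5 contiguous blocks and WHAM is re-run
per block.

## What the looping model predicts

For unbent DNA the J-factor has the textbook interior maximum (the test
suite verifies it falls between 300 and 700 bp; the measured curve peaks
near 450 bp). For a rigid 150° mid-loop kink the model predicts $J$ to
*increase monotonically* toward short loops across the 50–600 bp range:
the kink's ground state already brings the ends to 0.26× the contour, so
closing to 2 nm is nearly free energetically at every length in that range
and the gain is the shrinking entropic search volume (~$1/L^2$). The
geometric cutoff (reachable maximum below 2 nm) only bites below ~25 bp.
The experimental short-loop population at ~100 bp therefore additionally
reflects features absent from this minimal model — most plausibly the
protein footprint occupying part of the loop, variability in bend position,
or orientation constraints at capture. We deliberately do not add such
ingredients: the module implements the minimal stated model, and the
two-population histogram fit (`predict_loop_size_distribution()`) treats
the curves only as shapes to be scaled.

A second documented limit: the Gaussian-chain closed form
$(3/4\pi L_p L)^{3/2}$ is only asymptotic. At $L = 10 L_p$ the true WLC
contact density is ~30% below it (the well-known small-$r$ depletion of
semiflexible chains), and the converged simulator reproduces the WLC
value, not the Gaussian one — the suite's flexible-limit check is
therefore expected to sit several block-SEs below the Gaussian number
while the unbiased $\langle R^2\rangle$ agrees with the WLC closed form
to 1%.

# Stretching-trace analysis

Traces are block-averaged from 10 kHz to 1 kHz and boxcar-smoothed over
25 ms. Rupture candidates are local force maxima in (1, 60] pN — the upper
bound excludes overstretching — that rise ≥ 1 pN above the local pre-peak
minimum, drop ≥ 1 pN within 100 ms, and gain ≥ 10 nm of extension;
candidates within one drop window collapse to the single highest peak
(noise maxima riding the approach to a rupture would otherwise be counted
repeatedly), and terminal force collapses without recovery are classified
as tether breaks, censored at the 110 pN trap escape force when the tether
outlives the trap. Loop sizes are median contour-length differences over
50 ms windows on each side of the drop, excluding a 10 ms guard band.

The compaction observable — extension at 0.5 pN — is read from local linear
fits of force and extension against time around the first crossing: a raw
first-crossing systematically fires early on a slow noisy ramp (the
first noise excursion above threshold precedes the true crossing), which
would bias extension low by hundreds of nm at these ramp rates.

Tether survival under constant force is summarized by a double-exponential
fit to the empirical survival curve (Kaplan–Meier, so censored tethers
contribute to the at-risk set), minimizing squared error on the curve; the
half-life solves $S(t_{1/2}) = 1/2$ numerically. Curve fitting (rather than
censored maximum likelihood) is the default for fidelity to how such
distributions are usually plotted and fitted; over 200 replicate synthetic
datasets of 150 tethers the median half-life bias stays below 10%.

# Unzipping-trace analysis

Force–extension points are inverted to (force, bp-unzipped) curves and
smoothed over 25 ms. Curves are aligned to a reference baseline by integer
cross-correlation over protein-free regions (search radius ±200 bp,
elevated regions excluded from the match, ≥200 bp of overlap required).
The interaction range sums consecutive runs (≥ 5 bp, to suppress spikes)
where force exceeds the baseline by ≥ 2 pN before breakage; sub-threshold
gaps are not counted. Breakage probability is the fraction of tethers
breaking before 80% of the full length, with binomial standard error
$\sqrt{p(1-p)/n}$.

# Twisting-trace analysis

The hat curve is fit as a rounded quadratic cap joined continuously to two
linear flanks (five parameters: center, plateau, curvature, two cap
half-widths); this smooth piecewise form captures the buckling shoulders
without assuming symmetric slopes. Extension converts to turn state by
inverting the declared flank; turns relaxed follow by subtracting the
initial winding (±40 turns by default, held at 0.22 pN).

Pause detection follows the dwell-time procedure exactly: order-2
Savitzky–Golay filtering with a 30 s time constant (301 points at 10 Hz —
we read "non-linear 2nd-order" as the polynomial order), 0.2-turn binning
of turns relaxed, dwell per bin, clusters of adjacent bins with > 2 s
dwell each merged into single states, time-domain assignment within 0.4
turns, and refinement of level and duration by averaging the assigned
points. Two dwells are excluded by construction because they are not
pauses: the pre-activity origin (levels below 0.5 turns) and the terminal
relaxed plateau (analysis stops when the smoothed series first reaches
full relaxation minus one turn).

The pause-free rate implements the stated 5 s sliding-window analysis as a
single rolling 5 s linear fit on the raw turn series: the rolling fit *is*
the low-pass stage, and stacking it on an already-filtered series would
double the effective time constant and measurably bias burst-edge rates
low. Instantaneous rates over the first burst are binned into 0.5-turn
bins and the median over bins is returned. The pause frequency is the
reciprocal decay constant of an exponential fit to the survival histogram
of turns-before-first-pause, with pause-free traces censored at ~30 turns
(the pre-buckling onset of a 12.7-kb tether at 0.22 pN, taken as a
configured constant). The mean relaxation rate — whose exact definition is
not standardized — is defined here as total turns relaxed divided by the
time from recording start to first reaching the relaxed plateau, pauses
included, with never-relaxing traces flagged.

**Detection floor.** The 30 s filter and 2 s dwell threshold impose a hard
floor on detectable pause durations: on ground-truth traces the detector
finds essentially no pauses shorter than 5 s, a small fraction between 5
and 15 s, and ~90% above 15 s. With exponentially distributed pause
durations of 30 s mean (the generator default), a substantial minority of
injected pauses is invisible, so the recovered pause frequency
underestimates the injected one by roughly the miss fraction. This is a
property of the detection procedure itself, shared by any analysis of real
traces with the same constants; frequency recovery within ~15% requires
mean pause durations of roughly 100 s or more.

# Synthetic data: what it emulates and what it does not

The generators are first-class, seeded, and emit machine-readable ground
truth for closed-loop tests.

* `gen_stretch_trace()`: quasi-static constant-velocity stretching at
  200 nm/s on a 12,688 bp template — at each stage position the force
  solves the WLC relation for the currently stretched contour; loop
  ruptures are instantaneous single-sample contour jumps; Gaussian force
  noise (0.3 pN at 1 kHz). No bead/trap dynamics, hydrodynamics, or drift:
  adequate at 200 nm/s, but rise times and force overshoots of real
  instruments are absent, so detection-latency effects are untested.
* `gen_unzip_curve()`: additive force elevations over bound spans on a
  sequence-derived baseline, optional breakage at a force cap. Real
  unzipping sawtooth dynamics (stick–slip of the fork) are not simulated.
* `gen_twist_trace()`: catalytic strand-passage events as a Poisson
  process at rate (pause-free rate)/2 per second, each removing 2 turns;
  after each event a pause occurs with fixed probability, with exponential
  duration (mean 30 s); extension follows the hat model with 30 nm
  Gaussian noise at 10 Hz. Event stochasticity means the generator itself
  produces occasional > 2 s inter-event dwells, which the dwell-time
  detector legitimately flags; ground-truth "pauses" are only the
  deliberate ones.
* `gen_survival_lifetimes()`: i.i.d. two-component exponential mixture
  with right censoring.

Passing the closed-loop tests therefore demonstrates the *pipelines'*
correctness under the stated noise models; it does not validate instrument
calibration, drift handling, or non-idealities excluded above.

# Problem sizes used by the test suite

The suite runs the looping engine at 2×10⁵ production steps per window for
curve-level checks (block SEs of a few percent) and at the canonical
1.5×10⁶ steps for the single flexible-limit run; rupture recovery uses 200
synthetic traces, survival recovery 200 replicate datasets of n = 150, and
the pause pipeline 100 relaxation traces of 900 s at 10 Hz. The acceptance
script reruns the bent-DNA J-factor grid (50–600 bp, 2×10⁵ steps/window)
and a 4 kb baseline in about a minute.
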