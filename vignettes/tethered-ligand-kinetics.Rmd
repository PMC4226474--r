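---
title: "Tethered-ligand binding kinetics: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tethered-ligand binding kinetics: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegtether)
```

## The problem

T-cell receptors (TCRs) are triggered by peptide-MHC (pMHC) ligands that are
normally presented on an opposing membrane, so the interaction is
two-dimensional. Tethering pMHC to a rigid surface through flexible
poly(ethylene glycol) (PEG) linkers of increasing length hands the ligand a
growing range of motion in the third dimension, interpolating between 2D and
3D binding. Experimentally, T-cell activation (fraction of cells producing
IL2) falls as the linker gets longer; coarse-grained simulation attributes
this to slower binding on- and off-rates for longer tethers, with the tether's
entropic tension supplying a mechanical force on the bond.

`pegtether` implements the computational side of this programme:

1. closed-form polymer descriptors of PEG (unit count, contour length, Flory
   radius, entropic spring force, Rouse time);
2. a FRET model connecting coil size to measured donor quenching;
3. a Brownian-dynamics simulator of a tethered bead-spring chain binding an
   implicit surface, with event detection;
4. dwell-time kinetics (on/off rates, bootstrap intervals) and a
   potential-of-mean-force (PMF) analysis;
5. linear response-rate analysis tying activation data to coil size; and
6. seeded generators of synthetic data with retained ground truth, so every
   stage is testable end to end without external data.

## Polymer descriptors

A PEG of molecular weight $M$ has $n = M/44$ ethylene-oxide units of length
$a = 0.28$ nm (value for PEO in water). The package keeps $n$ unrounded for
all derived quantities and reports the integer count separately:

* contour length $L_c = n\,a$,
* Flory radius $R_F = a\,n^{3/5}$ (self-avoiding coil),
* Gaussian-chain tension $f = 3 k_B T\, x / (n a^2)$ at extension $x$,
* Rouse relaxation estimate $\tau_1 = b^2 N^2 / (3 \pi^2 D)$ for an
  $N$-bead discretisation.

```{r}
tb <- peg_linker_table()
tb$Lc_check <- round_half_up(sapply(tb$mw, contour_length), 1)
tb$RF_check <- round_half_up(sapply(tb$mw, flory_radius), 1)
tb[, c("linker", "mw", "contour_length_nm", "Lc_check",
       "flory_radius_nm", "RF_check")]
```

Every printed value reproduces at one decimal place except the Flory radius
of the shortest linker (PEG 88): the published 0.5 nm is inconsistent with
the power law the table itself states ($0.28 \times 2^{0.6} = 0.42$ nm). At
two monomers the "coil" is dominated by its maleimide/biotin end groups, so
the printed number may be a deliberate correction — but it does not follow
the formula, and the package follows the formula. This is a known, accepted
discrepancy.

Rounding convention: printed values are matched by half-up rounding at one
decimal (`round_half_up()`); the source does not state its convention, and
half-up is the only choice consistent with all rows we can check.

## FRET model

For a ligand held by a coil of Flory radius $R_F$ at a surface, the mean
donor-acceptor distance is modelled as $r = R_F + r_\mathrm{lig}$ with
$r_\mathrm{lig} = 2$ nm (pMHC radius), and transfer efficiency follows the
Forster form $E = 1/(1 + (r/R_0)^6)$ with $R_0 = 5$ nm for the
DyLight 549/649 pair. Measured efficiencies come from acceptor
photobleaching, $E = 1 - I_\mathrm{before}/I_\mathrm{after}$; noise can
invert the intensities, in which case the estimate is clamped to zero and
flagged rather than reported negative (the measurement literature is silent
on this; a negative efficiency is physically meaningless). Efficiencies are
compared after normalization to the shortest linker present, which removes
the unknown instrument scale:

```{r}
meas <- tb[!is.na(tb$fret_pct), ]
theo <- theoretical_fret(meas$flory_radius_nm + 2)
cor(normalize_series(theo), normalize_series(meas$fret_pct))
```

Linkers whose transfer is unmeasurable (beyond ~7.5 kDa, where
$r \gg R_0$) are represented as missing, not as zero.

## The tethered-chain simulator

`run_brownian()` integrates overdamped Langevin (Euler-Maruyama) dynamics of
a bead-spring chain whose first bead is fixed at height $h$ (default 9 nm)
above an implicit plane at $z = 0$:

* harmonic bonds (rest length $b$, stiffness 100 kT/nm^2);
* purely repulsive WCA excluded volume ($\sigma = 0.8\,b$, 1 kT) between
  beads two or more bonds apart;
* a one-sided harmonic wall at $z = 0$ (100 kT/nm^2), with typical thermal
  penetration $\sqrt{kT/k_\mathrm{wall}} = 0.1$ nm;
* an attractive well $U(z) = -\varepsilon (1 - (z/w)^2)^2$ on the terminal
  bead for $0 \le z < w$, default depth $\varepsilon = 7$ kT and range
  $w = 1$ nm, matching the binding-event cutoff.

The implicit plane replaces an explicit lipid bilayer deliberately: the
length effect under study is carried by chain entropy and steric access, not
by lipid chemistry, and an implicit surface is what makes a 20-replica sweep
tractable on one CPU. For the same reason the integrator is Brownian at
fixed temperature rather than a pressure-coupled MD ensemble: with no
explicit solvent there is nothing for a barostat to act on. A bead maps to
3 PEO units by default ($b = 0.84$ nm), which keeps the longest chains of
interest around 150 beads; results are reported against unit counts, never
bead counts. A well depth cannot be mapped uniquely onto the ~10 uM solution
affinity of the pMHC-TCR pair in this geometry, so only rate *ratios* across
lengths are interpreted, mirroring how the original analysis scales rates
against its shortest simulated polymer.

Units are reduced: energies in kT, lengths in nm, bead diffusion $D = 1$
nm$^2/\tau$. No calibration of $\tau$ to physical seconds is attempted —
within-sweep ratios are unaffected. `temperature_kT` (4.11 pN nm, 300 K)
enters only when converting PMF slopes to piconewtons.

Numerical choices:

* timestep $10^{-3}\,\tau$; the constructor enforces the resolution contract
  (per-coordinate RMS step below a tenth of the binding range) and warns if
  bonds are integrated too coarsely;
* the deterministic drift per step is capped at 0.1 nm, which tames the rare
  steep WCA overlap without touching equilibrium statistics measurably (the
  cap engages only in the far repulsive tail);
* runaway coordinates (beyond ten contour lengths) abort with a diagnostic;
* each replica has its own RNG stream spawned from the master seed, and its
  own freshly grown self-avoiding initial conformation; trajectories are
  bit-reproducible given a config;
* the default burn-in is ten Rouse times; the kinetics sweep uses one Rouse
  time, since its initial conformations are already near-equilibrium random
  walks and dwell statistics are collected in steady state.

Binding events use a two-threshold state machine (bind below 1.0 nm, unbind
above 1.5 nm) to suppress recrossing chatter; setting both cutoffs to 1 nm
recovers the single-cutoff definition exactly, and the two modes classify
the synthetic telegraph surrogate identically by construction.

## Kinetics estimation

`estimate_rates()` uses the reciprocal-mean-dwell (mean first-passage)
estimator, $k_\mathrm{on} = 1/\overline{t_\mathrm{unbound}}$,
$k_\mathrm{off} = 1/\overline{t_\mathrm{bound}}$, with seeded percentile
bootstrap intervals; it is robust at the modest event counts a desk-scale
sweep produces. First and last intervals are censored and excluded by
default. A censoring-aware exponential maximum-likelihood variant
(`method = "exponential"`, $k = n_\mathrm{complete}/\sum t$ including
censored time) is provided and is the default inside
`sweep_chain_lengths()`: at realistic replica durations a large share of
bound dwells is cut off at replica boundaries, and discarding that censored
time would bias both rates upward. For complete data the two estimators
coincide.

The PMF is a histogram estimate $W(z) = -kT \ln p(z)$ (0.1 nm bins, minimum
shifted to zero, empty bins masked). The "force at the most probable binding
distance" is reported as the slope of the *tether-chain* PMF there: the
binding-well energy is subtracted before differentiating
(`subtract_potential`), because the slope of the total PMF at its own mode
is zero by construction and carries no information. What remains after
subtraction is the entropic tension the chain applies to the bond — the
mechanically meaningful quantity, inversely proportional to chain length in
the Gaussian limit (`entropic_extension_force()` gives the closed-form
cross-check). Absolute forces at this resolution are indicative only; the
published ~40 pN figure depends on a force field this package deliberately
does not reproduce.

## The desk-scale length sweep

```{r, eval = FALSE}
sw <- sweep_chain_lengths(c(15, 30, 60), time_per_replica = 600,
                          n_replicas = 20, equilibration_factor = 1,
                          seed = 42)
```

The sweep runs 20 replicas of 600 tau production per arm (about ten minutes
on one CPU), pools dwells across replicas, and scales rates against the
shortest chain. Two findings are robust at this scale and match the
underlying science: the off-rate falls with chain length (longer tethers pull
less hard on the bond, so it survives longer), and the tether tension at the
bound position falls with length.

Two findings are *not* reachable at this scale, and the corresponding
acceptance-style expectations fail honestly rather than being relaxed:

* **The 15-bead arm produces no events.** Its mobile contour (11.8 nm)
  barely exceeds the 9 nm tether height, so reaching the 1 nm binding zone
  costs ~10 kT of stretching entropy; the expected first-passage time
  (~10^6 tau) exceeds the simulated time by orders of magnitude. The
  original simulations started at PEG 4000 — a 31-bead chain, the
  equivalent of our middle arm — and never probed a slack-free length.
* **A strictly decreasing on-rate across all three arms.** With an implicit
  plane, a short chain binds *more rarely* than a long one (reach-limited
  regime), so the decreasing on-rate seen with an explicit bilayer — where
  polymer crowding at the surface throttles access for long chains — cannot
  be reproduced by chain entropy alone over this length range. Between the
  30- and 60-bead arms (both with ample slack) the measured on-rate does
  fall, driven by the chain's slower relaxation.

## Response-rate analysis

Activation time courses (fraction of IL2-producing cells, hourly over six
hours, three independent experiments) are normalized within each experiment
to that experiment's maximum, then fitted by ordinary least squares with a
free intercept, pooling normalized values across experiments; the slope is
the response rate. A per-experiment fit is available by subsetting, but the
pooled fit is the default because per-experiment normalization already
removes the scale differences that would otherwise demand separate fits.
`correlate_rates()` reports Pearson and Spearman coefficients between
response rates and any paired per-linker quantity (Flory radius, scaled
simulated rates) and emits the rates scaled to a reference linker.

## What the generators emulate — and what they do not

* `gen_telegraph()`: alternating exponential dwells with known rates, plus a
  two-level height surrogate (0.5 / 3 nm, 0.05 nm jitter) whose levels are
  far from both detection cutoffs, so single- and dual-cutoff detection
  agree on it exactly. It validates estimator calibration, not chain
  physics: real dwell distributions need not be exponential.
* `gen_fret_intensities()`: multiplicative Gaussian noise on intensity
  pairs. Real photobleaching adds spatial heterogeneity and bleed-through
  that are not modelled.
* `gen_response_curves()`: linear-in-time normalized responses with additive
  noise, clipped to [0, 1]; with default slopes and noise the clip bias on
  fitted slopes is below 1% (verified in the tests). Real dose-response
  saturation and cell-to-cell variability are not modelled.

Passing tests on these generators demonstrates that the estimators are
correctly implemented and calibrated — not that the biological data obey the
generating models.

## Problem sizes used by the test-suite

Chosen once, as the package's own desk-scale conditions: telegraph grid
9 x 10^4 events; bootstrap coverage 100 repetitions of 1000 events with 500
resamples; kinetics sweep 3 lengths x 20 replicas x 600 tau; free-chain
scaling 10/20/40 beads, 30 Rouse times each over 4 replicas. The package's
interface is its functions and this vignette; no shell entry point is
shipped.

## Known limitations

* No hydrodynamic interactions, no explicit lipids or proteins, no absolute
  time or force calibration; cross-length ratios are the unit of meaning.
* The dwell-based estimators assume a two-state reduction; intermediate
  heights are assigned by the cutoff state machine.
* The Gaussian spring law is an order-of-magnitude tool near full extension.
* Short linkers (two monomers) sit outside the scaling laws' domain of
  validity, as the PEG 88 discrepancy above illustrates.
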