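---
title: "Targeted middle-down quantification of H3K4 methylation within H3 acetyl states"
author: "h3tailquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted middle-down quantification of H3K4 methylation within H3 acetyl states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h3tailquant)
```

## The measurement problem

Histone H3 tails carry combinatorial modifications: lysine acetylation at
K9/K14/K18/K23/K27 and methylation at K4. Bottom-up proteomics destroys the
combinatorial information (tryptic peptides separate the sites), while
intact-protein analysis struggles with near-isobaric species. Middle-down
analysis of the Glu-C N-terminal peptide — residues 1–50, cleaved
C-terminal to the first glutamate, E50 — keeps all six sites on a single
~5.3 kDa analyte, and a *targeted* scheme makes the key question tractable:
what is the K4 methyl stoichiometry (me0/me1/me2/me3) *within* each acetyl
degree (0ac–5ac)?

The scheme exploits three facts this package encodes:

* **Chromatographic separation by acetyl degree.** Each added acetyl
  removes a positive charge, shifting reversed-phase retention; the six
  degrees elute in distinct windows (defaults: 0ac 35–40, 1ac 45–55,
  2ac 55–60, 3ac 62–68, 4ac 69–73, 5ac 74–78 min).
* **A common precursor window.** All proteoforms of interest fall, at the
  9+ charge state, inside a single narrow MS1 range (585–640 m/z);
  precursor m/z confirms the acetyl degree coarsely.
* **A site-resolved reporter ion.** ETD c-ions retain side-chain
  modifications, and c4 covers exactly A-R-T-K4: its four methyl variants
  (nominal m/z 474, 488, 502, 516, all within the narrow 470–530 ion-trap
  MS2 range) report K4 stoichiometry directly, independent of the acetyl
  state, because every acetylatable lysine lies beyond residue 4.

## Mass model

Masses are monoisotopic throughout. A proteoform's mass is the sum of its
residue masses plus one water plus additive PTM deltas (me1 14.015650,
me2 28.031300, me3 42.046950, ac 42.010565 Da). The near-isobaric pair
me3/ac differs by 0.036385 Da — resolvable at the peptide level at high
resolution, but at 9+ the difference is 0.0040 m/z units, far below any
practical precursor tolerance. The precursor filter therefore *cannot*
distinguish, say, 3ac + K4me3 from 4ac + K4me0; retention time is the
primary classifier of acetyl degree and the precursor check only rejects
grossly wrong isolations. This is why the extraction targets (the c4
quartet) are the quantitative readout, not precursor intensities.

c-ions are computed as the first *k* residues plus NH₃, protonated:
`(Σ residues + Σ PTM deltas at positions ≤ k + 17.026549 + z·1.007276)/z`.
Comparisons to nominal integer m/z use round-half-away-from-zero.

The peptide boundary deserves a note: Glu-C cleavage of H3.1 yields
residues 1–50 as the N-terminal peptide (E50 is the first glutamate), and
the resulting 9+ precursor (594.13 m/z unmodified, up to 622.14 for
5ac + K4me3) is consistent with the 585–640 acquisition window — the
consistency check is part of the test suite. N-terminal protein
acetylation and K4 acetylation are excluded from the enumerated
quantification space (the assay quantifies K4 *methyl* states); K4ac
remains representable by the proteoform type itself.

## Synthetic runs and what they emulate

`simulate_run()` generates a labelled run from a `mixture_spec` (per-degree
abundance + K4 stoichiometry vector π). Design choices:

* **Half-open RT windows** `[start, end)`: the 1ac/2ac boundary at exactly
  55 min deterministically belongs to 2ac.
* **Peak shape**: a symmetric Gaussian bell (SD `peak_width`, default
  1 min) multiplies all four quartet intensities equally, so stoichiometry
  is invariant to elution position; this is what makes the noise-free
  round trip exact.
* **Noise model**: multiplicative lognormal with unit mean (parameter =
  CV), reflecting the heteroscedastic intensity noise of trapping
  instruments, plus a uniform additive baseline that also populates
  off-target background peaks (these exercise the SNR-based scan
  curation). With CV = 0 and baseline = 0 intensities are exactly
  proportional to abundance × π.
* **Replicate structure**: `simulate_timecourse()` draws mixture-level
  perturbations per *biological* replicate (`bio_cv`) and fresh
  acquisition noise per *technical* replicate, mirroring a
  two-technical-within-three-biological design with butyrate-style time
  points (0, 10, 20, 30, 60, 120 min).
* **Monoisotopic sticks by default**; an optional binomial-carbon isotope
  envelope exists but is off — envelopes spread every quartet member by the
  same fractions and thus do not change stoichiometry.
* The MS2 cadence is configurable (default 1 scan / 2 s); the real
  instrument's scan rate is not a published quantity, and cadence only
  changes how many scans are averaged, not the expected stoichiometry.

What the simulator does **not** emulate: chimeric spectra, retention-time
drift, dynamic exclusion, charge-state interference, and ion statistics at
very low abundance. Passing recovery tests on synthetic data therefore
demonstrates the correctness of the *pipeline arithmetic* (selection,
averaging, extraction, normalization, aggregation) under a plausible noise
model — not robustness to every pathology of real chromatography.

## The quantification pipeline

Per acetyl degree: MS2 scans are kept when their retention time falls in
the window and their precursor is within ±0.05 m/z of one of the four
allowed 9+ targets; scans whose summed quartet intensity is below
`snr_min` (default 3) times the median off-target intensity are dropped —
a deterministic stand-in for manual curation of low-signal scans (e.g.
5ac at early time points). Survivors are averaged on a fixed 0.1-m/z bin
grid (ion-trap resolution); the intensity at each target is the maximum
binned intensity within ±0.3 m/z (a sum-within-tolerance variant is
available), and the quartet is normalized to 100 %. Empty windows
propagate as explicit missing cells, never zeros.

Aggregation averages technical replicates within each biological
replicate first; mean and SEM are then taken across biological replicates
(n = biological replicates; SEM is NA for n = 1). Condition comparisons
use the Student pooled-variance two-tailed t-test by default (Welch by
flag), reporting raw p-values (Benjamini–Hochberg by flag); two identical
zero-variance groups give p = 1 by convention, and zero variance with
unequal means raises an explicit degenerate-variance error rather than an
infinite t.

One statistical subtlety is worth recording: with three biological
replicates the recovered-minus-truth error divided by the estimated SEM
follows a t distribution with 2 degrees of freedom, whose tails are heavy
(|t₂| exceeds 3 about 10 % of the time). The test suite therefore checks
3-SEM *coverage across* the 24 stoichiometry cells (plus an absolute
3-percentage-point cap) rather than demanding every single cell fall
within 3 SEM, and separately checks that the mean absolute error over 100
seeded simulations at CV 0.15 stays below 3 percentage points.

## Kinetics

`fit_kinetics()` pools replicate points (the alternative — fitting
replicate means — discards within-dose information) and fits Hill and
Michaelis–Menten by unweighted Levenberg–Marquardt least squares
(`minpack.lm`), with starts Vmax₀ = max(v), K₀ interpolated at half-max,
h₀ = 1, and five jittered restarts on non-convergence. Substrate enters in
nM (titrations such as 400 → 23.4 nM in 1.5-fold steps, generated by
`make_titration()` to 3 significant figures) and K₀.₅ is reported in µM;
k_cat = Vmax/[E]. The extra sum-of-squares F-test compares the nested
pair; since the models are nested, SS(Hill) ≤ SS(MM) and F ≥ 0 always.
Numerical tie-break: when the restricted model already fits to within
numerical noise (RSS ≤ 1e-14 × Σv², as on noise-free h = 1 data) the F
statistic is defined as 0 and p as 1 — the ratio of two near-machine-zero
residuals is otherwise meaningless. Fits are unweighted because the assay
provides no replicate-level variance model; a weighting hook would be the
first extension for heteroscedastic count data.

The "n.d." screen reproduces the reporting convention for substrates
without measurable turnover: a dataset is non-determinable when the
one-sided t-test of top-concentration signal against background is
non-significant or when the Vmax confidence interval includes zero; the
CLI report writes the literal string "n.d.".

The F-test's nominal behaviour is verified empirically: on
Michaelis–Menten null data with Gaussian noise at 5 % of Vmax, the
rejection rate over 1000 seeded simulations must sit inside the binomial
95 % interval around 0.05. Hill-coefficient recovery is checked at
h ∈ {1.2, 1.7, 2.0} with 50 seeds per value (median within 15 % of
truth); 50 seeds keeps the default suite fast and is ample for a median.

## Dose-response

`fit_4pl()` fits y = bottom + (top − bottom)/(1 + (EC50/Q)ᴴ) after hook
exclusion: with q* the concentration of maximal mean signal, points at
Q > q* are dropped iff their mean falls below (1 − hook_frac) × max
(default hook_frac 0.1). The EC50 is *relative* — the inflection between
the fitted, unconstrained plateaus — matching the use of the fitted
hillslope in EC_F = (F/(100−F))^(1/H) × EC50rel (so EC₅₀ ≡ EC_F at
F = 50, and EC₈₀ = 4^(1/H) × EC50rel). Flat series are refused and flagged
no-binding instead of producing meaningless parameters; fold comparisons
between targets propagate EC50 uncertainty to first order and return an
explicit incomparable marker when either side is no-binding. Replicates
(typically duplicates) are all retained in the residuals; the bottom
plateau can optionally be fixed to a no-target background mean.

## Numbers the package stands behind

Every empirical statement above is recomputed by the test suite or by
`scripts/acceptance.R` at run time: the c4 quartet rounding to
474/488/502/516; the precursor-window consistency checks; the exact
noise-free round trips (stoichiometry to 1e-9, Hill and 4PL parameters to
1e-6); the F-test calibration; and the 100-seed recovery error. Simulation
sizes in the default suite (15-s scan cadence without MS1 scans for the
repeated-recovery loops; 50 seeds per Hill value; 1000 null simulations)
are the package's chosen benchmark sizes; the full-cadence defaults
(2-s interval, MS1 + MS2) remain what `acquisition_config()` ships with.

## Known limitations

* Quantification is deliberately confined to K4 within the c4 ion; no
  other site is localized, and no proteoform search engine is provided.
* Acetyl-degree assignment rests entirely on the configured RT windows; a
  run with shifted chromatography must have its windows re-specified (no
  alignment is attempted).
* The hook rule is empirical; no bead-chemistry model stands behind it.
* Kinetic fits are single-substrate and steady-state; no mechanistic
  cooperativity model (MWC/KNF) or me1→me2→me3 processivity is included.
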