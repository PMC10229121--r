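# h3tailquant

Quantitative tools for studying how histone H3 tail acetylation couples to
H3K4 methylation, built around three kinds of measurement:

1. **Targeted middle-down mass spectrometry.** The H3 N-terminal tail
   (Glu-C peptide, residues 1–50) is analyzed intact at its 9+ charge state
   (MS1 window 585–640 m/z). Acetyl degrees 0ac–5ac separate
   chromatographically and are selected by retention-time window; ETD MS2
   spectra are averaged per acetyl state and the **C4⁺¹ fragment ion
   quartet** — c4 ions at nominal *m/z* 474 (K4 unmodified), 488 (me1),
   502 (me2), 516 (me3) — reads out the K4 methyl stoichiometry *within*
   each acetyl degree. The package computes all proteoform and fragment
   masses exactly, selects/averages scans, normalizes the quartet to
   percentages, aggregates technical-within-biological replicates
   (mean ± SEM), and compares conditions by two-tailed t-test.
2. **Steady-state methyltransferase kinetics.** Velocity titrations are fit
   to both Michaelis–Menten, v = V·S/(K + S), and the Hill equation,
   v = V·Sʰ/(K₀.₅ʰ + Sʰ), with an extra sum-of-squares F-test deciding
   whether cooperativity (h ≠ 1) is supported. k_cat = Vmax/[E]; datasets
   whose signal is indistinguishable from background are flagged "n.d.".
3. **Bead-proximity (Alpha) dose-response.** Binding series are fit with a
   four-parameter logistic, y = bottom + (top − bottom)/(1 + (EC50/Q)ᴴ),
   after excluding post-maximum "hook" points; relative EC50 generalizes to
   any response fraction via EC_F = (F/(100−F))^(1/H) · EC50rel.

A synthetic-data generator produces ground-truth-labelled runs, velocity
tables and binding series for every stage, so the whole pipeline can be
benchmarked against known truth.

## Worked example

```r
library(h3tailquant)

# exact proteoform arithmetic
p <- proteoform(H3_1_50, c("4" = "me3", "9" = "ac", "14" = "ac", "18" = "ac"))
proteoform_mass(p)                    # 5506.1462 Da
ion_mz(p, "precursor", charge = 9)    # 612.8013 Th (inside 585-640)
round(c4_targets(), 4)
#>      me0      me1      me2      me3
#> 474.3147 488.3303 502.3460 516.3616

# simulate a noisy targeted run and recover the K4 stoichiometry
run <- simulate_run(example_mixture(), acquisition_config(noise_cv = 0.15),
                    seed = 42, metadata = list(condition = "butyrate",
                                               time_min = 60, bio = 1L,
                                               tech = 1L))
quantify_run(run)
#>   condition time_min bio tech acetyl_degree   me0    me1    me2     me3 n_scans
#> 1  butyrate       60   1    1             0 91.89  6.124  1.493  0.4889     150
#> 2  butyrate       60   1    1             1 79.49 14.393  4.101  2.0186     300
#> ...
#> 6  butyrate       60   1    1             5 18.34 26.724 30.381 24.5567     120
```

Each row is the percent occupancy of K4 me0/me1/me2/me3 within one acetyl
degree (rows sum to 100); compare with the generating truth in
`example_mixture()` — at 15 % acquisition noise the recovered percentages
sit within a few tenths of a point of truth because hundreds of scans are
averaged per window.

```r
# cooperative kinetics with model selection
ds <- simulate_kinetics(K05 = 120, kcat = 0.03, h = 1.7, E = 4,
                        S = make_titration(400, 1.5, 8),
                        noise_sd = 0.002, n_rep = 3, seed = 7)
fit_kinetics(ds, E_nM = 4)
#> <kinetic_fit_set>
#>   MM   K_0.5 = 0.306 uM, k_cat = 0.0503 min^-1, h = 1,    R^2 = 0.9792
#>   Hill K_0.5 = 0.121 uM, k_cat = 0.0307 min^-1, h = 1.68, R^2 = 0.9968
#>   extra sum-of-squares F(1,24) = 131.6, p = 3.144e-11 -> Hill
```

The F-test prefers the Hill model and recovers K₀.₅, k_cat and h close to
the generating values (0.12 µM, 0.03 min⁻¹, 1.7).

```r
# dose-response with relative EC50 and EC80
bs <- simulate_binding(100, 10100, ec50 = 10, hillslope = 1.2,
                       Q = c(0.37, 1.1, 3.3, 10, 30, 90, 270),
                       noise_cv = 0.05, seed = 3)
f <- fit_4pl(bs)    # EC50rel = 10.78 nM, H = 1.1, R^2 = 0.9987
ec_f_rel(f, 80)     # 38.22 nM
```

A command-line surface wraps the same functions
(`inst/cli/h3tailquant.R`): subcommands `simulate`, `quantify`,
`kinetics-fit` and `dose-fit`, each writing its outputs plus a manifest
(inputs, config hash, seed, package version).

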