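# amytrap

Quantitative analysis of designed β-strand peptide-trapping binders and
their effect on amyloid formation.

De novo designed "peptide-trap" proteins present a β-sheet cleft that
engulfs a short β-strand (or β-hairpin) of a target peptide. Because the
cleft buries one face of the bound strand, only certain residues fit at
the solvent-inaccessible positions — which makes it possible to retarget a
design to natural amyloidogenic sequences (Aβ42, serum amyloid A1, tau,
transthyretin) by scanning for sequence windows whose burial pattern the
slot tolerates. Binders retargeted this way trap the amyloid monomer and
can dramatically slow fibril formation. This package implements the
quantitative side of that workflow for structural bioinformaticians and
aggregation-kinetics practitioners:

- **Burial-pattern scanning** (`scan_sequence`, `thread_match`): slide a
  window of the slot length *n* over a target sequence and keep frames
  whose buried positions carry only {F, A, M, I, L, V, S, T, Y, G} and
  whose internal exposed positions avoid proline.
- **1:1 binding models** (`fit_steady_state`, `fit_kinetic_global`,
  `fit_mds_quadratic`): closed-form biosensor (BLI) kinetics
  R(t) = R_eq (1 − e^−(k_on C + k_off)t) and steady state
  R = R_max C/(C + K_d), plus the exact ligand-depletion quadratic
  C = [(L+B+K_d) − √((L+B+K_d)² − 4LB)]/2 for microfluidic diffusional
  sizing, fitted by multi-start Levenberg–Marquardt least squares.
- **Aggregation kinetics** (`simulate_aggregation`, `half_time`): the
  nucleation–elongation–secondary-nucleation moment model
  dP/dt = k_n m^n_c + k₂ m^n₂ M, dM/dt = 2 k₊ m P, m = m_tot − M,
  integrated numerically.
- **Inhibition inference** (`normalize_tht`, `fit_uninhibited`,
  `predict_sequestration_only`, `fit_secondary_modulation`,
  `potency_concentration`): normalize ThT traces, fit the identifiable
  rate products k_n k₊ and k₂ k₊ to uninhibited curves, quantify how much
  of the inhibition monomer sequestration alone explains, fit the
  suppression of secondary nucleation, and report potency as the binder
  concentration that lengthens the aggregation half-time t½ by 50%.
- **Synthetic assays** (`gen_tht_dataset`, `gen_bli_dataset`,
  `gen_mds_dataset`): seeded generators with the statistical structure the
  fitters assume, each bundling its generating truth, so the whole
  pipeline is testable end to end without instrument data.

## Worked example

Scan the bundled Aβ42 sequence with a default length-9 slot template, fit
a binder affinity from a synthetic sizing titration, then run the
inhibition pipeline on synthetic ThT data:

```r
library(amytrap)

ab <- load_targets()$Abeta42
scan_sequence(default_templates()$ss9b, ab)
#> <burial_matches> 7 match(es), 34 frame(s) evaluated
#>   protein start end strand    window template buried_residues
#> 1 Abeta42    28  36      + KGAIIGLMV     ss9b            GIGM
#> ...
#> 7 Abeta42    34  42      + LMVGGVVIA     ss9b            MGVI
```

All matches fall in the aggregation-prone C-terminal stretch
KGAIIGLMVGGVVIA — the slot engages at most 9 of the 42 residues.

```r
mds <- gen_mds_dataset(seed = 1, Kd = 83e-9, Ltot = 10e-9, sigma = 0.03)
fit_mds_quadratic(mds$conc_M, mds$fraction_bound, Ltot = 10e-9)
#> <mds_fit> 1:1 binding fit (converged)
#>       estimate       se
#> Kd 8.24602e-08 3.44e-09
```

The 83 nM generating affinity is recovered at 82.5 nM despite 3% noise,
because the fit uses the exact depletion quadratic rather than the simple
isotherm (the labeled species sits at a concentration comparable to K_d).

```r
res <- run_pipeline(list(seed = 1, synth = list(
  binder_concs = c(0, 2.5e-7, 5e-7),
  k2_factors = data.frame(conc = c(2.5e-7, 5e-7), factor = c(0.5, 0.2)))))
res$inhibition
#> <inhibition_fit> sequestration + secondary-nucleation modulation (table mode)
#>   binder Kd = 8.3e-08 M, monomer = 2e-06 M, uninhibited t1/2 = 9.01e+03 s
#>   binder_conc_M factor bound_frac excluded   rss t_half
#> 1       2.5e-07 0.4692      0.119    FALSE 1.180  13630
#> 2       5.0e-07 0.2125      0.237    FALSE 0.837  20610
res$potency_M
#> [1] 2.45e-07
```

The generating secondary-nucleation factors (0.5 and 0.2) are recovered as
0.47 and 0.21; at 250 nM binder only 12% of the 2 µM monomer is
sequestered, so the measured slowdown (t½ from 9,010 s to 13,630 s) is
mostly due to suppression of secondary nucleation — the same dissection
the analysis performs on real ThT data. The potency readout says 245 nM
of this binder lengthens t½ by 50%.

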