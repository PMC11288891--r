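---
title: "Models and methods behind amytrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amytrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amytrap)
```

This vignette explains the models the package implements, the conventions
and numerical choices behind them, and what the synthetic-data generators
do and do not emulate. It is the reference for every tunable that matters.

## Burial-pattern scanning

A designed peptide-trap binder engulfs a β-strand of *n* residues in a
cleft. One face of the strand points into the scaffold core, so the
residues at those window positions are sterically restricted; the other
face is solvent-exposed and nearly unrestricted. The scanner encodes this
as a `burial_template`: a window length and a set of buried positions.
A window of a target sequence matches when

* every buried position carries one of F, A, M, I, L, V, S, T, Y, G
  (small and/or hydrophobic residues that fit a β-sheet core), and
* no internal exposed position carries proline, which cannot adopt the
  extended backbone conformation; proline is tolerated only at the two
  window ends.

All `L − n + 1` frames are evaluated at stride 1 and overlapping matches
are all reported. Sequences are scanned in the forward orientation by
default; a strand can in principle insert into a cleft in either
direction, so a `reverse` flag exists, off by default, reporting
minus-orientation hits on forward coordinates.

Conventions and open choices:

* **Coordinates are 1-based inclusive throughout**, the native R (and
  biologist-facing) convention.
* **Burial masks are user data.** Masks are read off each design's
  structural model, so none is canonical. The bundled defaults use the
  alternating periodicity of a β-strand bound edge-on: positions
  {1,3,5,7} for n = 8 and the two registers {1,3,5,7,9} / {2,4,6,8} for
  n = 9. Real designs can deviate; pass your own `burial_template`.
* **Hairpin slots** bind two strands joined by a turn. The structure of
  the turn is not part of the burial pattern, so `scan_hairpin` treats a
  hairpin as two independent windows separated by a configurable loop
  length (default 2–6 residues). This two-window treatment is a package
  convention, not a structural claim.
* `thread_match` performs a full substitution of the template peptide by
  the matched window — by construction the threaded peptide re-matches
  its template, which the test suite verifies for every match of every
  bundled target.

The four bundled targets (Aβ42, SAA1, a tau fragment spanning the
microtubule-binding repeats, transthyretin) are the standard scan set;
`gen_scrambled_targets` provides composition-preserving shuffles as a
null model for match counts.

## 1:1 binding models

All concentrations are molar and times seconds internally; CSV columns
declare units in their names (`time_s`, `conc_M`) and no unit guessing is
ever attempted.

**Biosensor (BLI) kinetics.** The 1:1 model
`dR/dt = kon·C·(Rmax − R) − koff·R` has closed forms for both phases:
association `R(t) = Req(1 − e^−(kon·C+koff)t)` with
`Req = Rmax·C/(C + Kd)`, and dissociation `R(t) = R0·e^−koff·t`. The test
suite checks the closed forms against a numerical ODE solution to 1e−8.
`fit_kinetic_global` fits all concentrations **globally** with one shared
(kon, koff, Rmax) — per-trace fitting hides inconsistencies a global fit
exposes — and ties dissociation to the model-predicted response at the
end of association. An optional shared linear drift term exists because
real sensorgrams drift; it is off by default since no drift model is part
of the core analysis. Reported `Kd = koff/kon`. When fitting a
steady-state response from real traces, the equilibrium response is taken
as the mean over the last 5% of the association window (the CLI's
`fit-bli --mode steady`), a stated convention for assays run "until
equilibrium is approached".

**Ligand depletion.** Sizing assays track a labeled species at
concentrations comparable to Kd, so the excess-ligand isotherm is wrong:
its apparent midpoint approaches `Ltot/2 + Kd` rather than `Kd`. The
package therefore always computes the complex concentration from the
mass-balance quadratic, in the numerically stable form
`C = 2LB / (S + sqrt(S² − 4LB))`, `S = L + B + Kd`, which avoids the
cancellation the textbook form suffers when `Kd ≫ L, B`. The same
function provides the **monomer sequestration** calculation used by the
aggregation module.

**Optimizer.** All fits use Levenberg–Marquardt (trust-region) least
squares in log10(Kd) (and log10 rate) space with five log-spaced Kd
starts spanning the concentration range, keeping the best converged
solution. Standard errors come from the Gauss–Newton Hessian at the
optimum; Kd errors are mapped from log space by the delta method.
Non-convergence is an explicit error, never a silent result, and
titrations that cannot bracket the fitted Kd (all concentrations more
than 10× above or below it) set an identifiability warning in the
diagnostics.

## Aggregation model

Fibril formation is modeled by the standard two-moment system over fibril
number P and fibril mass M:

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M,\qquad
  \frac{dM}{dt} = 2 k_+ m P,\qquad m = m_{tot} - M .$$

Primary nucleation creates nuclei from monomer; secondary nucleation
creates them on fibril surfaces (the dominant autocatalytic pathway for
Aβ42); elongation adds monomer at both fibril ends (hence the factor 2,
configurable via `ends`). The module integrates these ODEs numerically
(`lsoda`, rtol 1e−8) rather than coding the closed-form integrated rate
laws: numerics cover seeded and inhibited cases uniformly, and the
early-time closed-form limit `M(t) ≈ k_+ k_n m_tot^{n_c+1} t²` (for
k₂ = 0) is retained as a test oracle only. Default reaction orders
`nc = n2 = 2` are the standard choice for Aβ42 in this framework.

The default rate constants (`kn = 1e-4`, `kplus = 3e6`, `k2 = 1e4`, molar
and seconds) are **order-of-magnitude placeholders**, chosen once to give
a realistic half-time of ≈2.5 h at 2 µM monomer; they are not measured
constants, and every analysis that matters fits its own rates.

`half_time` locates the first crossing of half the final plateau by
linear interpolation; a curve whose mass still rises by more than 1% of
the plateau over the last tenth of the window is rejected as incomplete
rather than silently extrapolated. `half_time_scaling` returns the
log–log exponent γ = d log t½ / d log m_tot, the standard mechanistic
diagnostic (≈ −(n₂+1)/2 = −1.5 when secondary nucleation dominates with
n₂ = 2).

**Inhibition couplings.** A monomer-binding inhibitor enters in two ways:

1. *Sequestration*: bound monomer is treated as removed for the whole
   reaction. The effective monomer is the free monomer of the exact 1:1
   equilibrium, computed **once at t = 0**; dissociation of the complex
   over the aggregation timescale is neglected. Sequestration-only
   simulation is therefore *exactly* (bit-for-bit) an uninhibited
   simulation at the reduced monomer concentration.
2. *Secondary-nucleation suppression*: k₂ is multiplied by a
   concentration-dependent factor in (0, 1], either a per-concentration
   table (interpolated in log-factor across concentration, saturating
   beyond the last entry) or the parametric form `1/(1 + [I]/K_I)`. The
   table is the default because it makes no assumption about the
   functional form.

A dynamic re-equilibration mode (recomputing the monomer–binder
equilibrium along the trajectory) and Michaelis-type saturation of
secondary nucleation are deliberately absent from the core model; both
are extensions the analysis does not require.

## ThT inference pipeline

ThT fluorescence reports fibril mass linearly: `F = a·M(t) + b` with
per-well constants. The pipeline mirrors the experimental narrative and
fits **sequentially** — uninhibited rates first, then modulation —
because the uninhibited curves alone determine the rate products and the
sequential fit keeps each inference interpretable.

* **Normalization** subtracts the mean of the first 5 points and divides
  by the plateau amplitude (mean of the last 5 points minus baseline). A
  trace that never levels off — typical for strongly inhibited wells —
  borrows the mean uninhibited plateau amplitude so all conditions share
  a common scale; which convention applied is recorded per trace, because
  the two conventions put the data on different scales
  (fraction-of-available vs fraction-of-total monomer) and model
  comparisons must match. The 5-point baseline convention carries a small
  (~1e−4 to 1e−3) bias from early fibril mass; tests assert affine
  invariance exactly and absolute recovery to that bias.
* **Uninhibited fit**: only the products `kn·k+` and `k2·k+` are
  identifiable from a mass curve, so those are fitted (log10 space,
  multi-start), with orders fixed. Per-trace affine normalization
  constants are profiled out inside the least-squares problem (variable
  projection), so the noise of the 5-point baseline/plateau estimates
  does not bias the rates.
* **Sequestration-only prediction** simulates the inhibited conditions
  with the modulation factor pinned at 1 and returns per-concentration
  residuals, so "sequestration alone is insufficient" becomes a number
  rather than a judgement.
* **Modulation fit** holds rates and sequestration fixed and fits one k₂
  factor per concentration (or K_I in parametric mode) by 1-D bounded
  least squares, with an explicit check of the factor-1 boundary.
  Conditions where more than 90% of the monomer is predicted bound are
  excluded and flagged: with the majority of monomer sequestered the
  remaining curve no longer constrains the fibril-surface mechanism. The
  0.9 threshold is a stated convention for "majority bound".
* **Potency** is the binder concentration at which t½ is increased by a
  configurable fraction (default 50%), found by bisection on log
  concentration after a monotonicity check; a dense-grid scan agrees to
  1% in the tests. Lower potency concentration = stronger inhibitor.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure the fitters assume*:
ThT traces as `a·M + b` plus additive Gaussian noise (default σ = 2% of
the uninhibited plateau — plate-reader noise is not published, so this is
a convention recorded in the ground-truth metadata) sampled every 165 s
at 2 µM monomer in triplicate; biosensor traces with additive noise and
optional linear drift; sizing titrations from the exact quadratic with
Gaussian noise of sd 0.03 on the fraction scale (additive on that scale
so zero-binder rows correctly read 0 ± noise). A single top-level seed
derives one substream per trace, making outputs byte-identical under a
fixed seed and individual traces independent of generation order.
Per-well signal constants are jittered a few percent, as between wells of
a real plate.

What they deliberately do **not** emulate: instrument artifacts beyond
linear drift, well-to-well evaporation or temperature gradients,
ThT-binding nonlinearity at high fibril loads, oligomer-phase signal, or
fibril-surface saturation. Passing recovery tests on this synthetic data
therefore demonstrates the *estimators* are correct and well-conditioned
at realistic noise, not that real traces obey the model — on real data
the residual structure itself is a diagnostic.

Problem sizes used in the shipped tests (kept modest on purpose: they are
statistical checks, not surveys): scanner–oracle equivalence on 10⁴
random template×sequence pairs, 2×10³ random mass-balance systems against
bisection, 60 random trajectory draws for conservation/monotonicity, 50
seeds per affinity for sizing recovery, 7–10 seeds for rate-product and
kinetic recovery medians.

## Known limitations

* The sequential (uninhibited → modulation) fit does not propagate rate
  uncertainty into the factors; a joint fit would, at the cost of
  opacity.
* Above ~80% predicted bound monomer the modulation factor is weakly
  identified even below the 90% exclusion cut, because the curve barely
  leaves its lag phase within a standard assay window; expect wide
  scatter there.
* The hairpin scan's two-window treatment ignores turn-sequence
  preferences entirely.
* Mass-transport-limited biosensor kinetics, multi-site binding and
  avidity are out of scope; fits to data with those features will show
  structured residuals, which is the intended failure mode.
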