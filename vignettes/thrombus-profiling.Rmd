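---
title: "Thrombus profiling: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thrombus profiling: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thromboprofiler)
```

## The assay and its readout

Shear gradients at a vessel stenosis can drive discoid platelets to
aggregate without soluble agonists — biomechanical platelet aggregation,
initiated by GPIbα–VWF catch bonds and reinforced by integrin αIIbβ3
binding to fibrinogen and VWF. The in-vitro counterpart is a rectangular
microchannel (200 × 50 µm by default) carrying an 80% stenosis hump,
perfused with anticoagulated whole blood at 18 µL/min while up to seven
fluorescence channels record thrombus growth and composition.

The package's central data object is the seven-dimension thrombus profile:
the platelet-channel intensity 450 s after onset (thrombus size, arbitrary
fluorescence units) and six biomarker intensities normalized by the
platelet signal (dimensionless enrichments), in the fixed order
`size, fg, vwf, psel, ps, eplus, act`.

## Hydrodynamics

`shear_field()` uses lubrication theory: at each axial station the flow is
treated as locally fully developed, giving a wall shear rate
$\gamma(x) = \frac{6Q}{w\,h(x)^2}\cdot\frac{1}{1 - 0.63\,h(x)/w}$ and
stress $\tau = \mu\gamma$. The side-wall correction factor keeps the
formula within 2% of the exact rectangular-duct Fourier-series solution for
aspect ratios $w/h \ge 4$ (the test suite checks this against an
independently coded series oracle). Lubrication replaces CFD deliberately:
it is analytic, fast, and at the default operating point lands within 10%
of the CFD value for this geometry (~930 vs ~857 dyn/cm²); that ±10% band
is the stated accuracy contract of the module. The hump profile is a
raised-cosine bump of 400 µm axial extent by default (a Gaussian is
selectable); only the apex gap, not the hump shape, drives the apex stress.

Defaults: viscosity 1.0 mPa·s (Newtonian, plasma-like; the rheology behind
the CFD reference value is not published, and 1.0 mPa·s reproduces it
within the contract band), density 1060 kg/m³ (whole blood, used only for
Reynolds numbers). `circular_equivalent()` implements only the
same-cross-sectional-area Poiseuille tube mapping; it does not attempt to
reproduce shear rates quoted for circular stenosis geometries whose shape
is not available.

## The synthetic study

`generate_study()` emulates the cohort structure the analysis assumes:
healthy young (n = 33), healthy older (14), hypertensive young (9) and
hypertensive older (13) — 69 subjects. Each subject's true profile is
baseline × cohort multipliers × log-normal noise. Log-normal noise keeps
intensities positive; the default CVs are 0.25 for size and 0.2 for
enrichments (between-subject), with a separate technical CV of 0.05 applied
by `measure_profiles()` (within-subject, cancelled by paired designs —
with subject-level CVs applied per measurement, a paired n = 5 drug design
would have no power, which is not how repeatable microfluidic readouts
behave).

Only effect *directions* and significance are reported for the real
cohorts, so the effect sizes are the generator's calibration: multipliers
`[1.8, 1.3, 1, 1, 1, 1.6, 1.5]` for both hypertension and aging, chosen
once so that the derived effect barcode at the study's sample sizes is
`[+ + 0 0 0 + +]`. The two factors compose multiplicatively in the
hypertensive-older cohort (two-way synergy is reported qualitatively but
unquantified; multiplicative composition is the simplest assumption
consistent with it).

Time courses (`simulate_timecourses()`) put the platelet channel on a
three-parameter logistic after a 30-s onset delay. Growth configurations:
healthy `t_half = 200 s, tau = 68 s` and hypertensive
`t_half = 250 s, tau = 85 s`, so the 95%-of-plateau time
($t_{1/2} + \tau\log 19$) lands at ~400 s and ~500 s respectively — the
feature `fit_growth()` recovers. The logistic amplitude is calibrated so
that the 3-frame readout at onset + 450 s equals the nominal size, making
the zero-noise round trip through `quantify_profile()` exact. Platelet
autofluorescence leaks into the 391-nm channel as a fixed fraction
(default 0.1) of the platelet signal; the generator applies it to the Fg
channel (405-nm excitation dye) and `quantify_profile()` subtracts it.

What the generator does **not** emulate: image formation and segmentation,
spatial thrombus heterogeneity, non-logistic growth shapes, hematocrit or
platelet-count variation, and any correlation structure between profile
dimensions beyond the shared cohort multipliers. Passing tests therefore
demonstrate that the *analysis* recovers what the generative model encodes
— parameter recovery, error control, determinism — not that real blood
behaves like the model.

## Inhibitors and dose–response

`apply_inhibitor()` scales size by the Hill residue and each barcode-marked
dimension by `factor^(2θ(C))`, where `θ(C) = 1/(1 + (IC50/C)^h)` is the
occupancy: no effect at zero dose, the configured per-trit factor (default
0.5 down, 1.5 up) exactly at the IC50, its square at saturation. This makes
every "−" dimension monotone non-increasing in dose, which is asserted as a
property test.

The Hill equation is implemented as
`R + (100 − R)/(1 + (C/IC50)^h)` with `h > 0`. The same model is often
written with `(IC50/C)^HillSlope`; for a *decreasing* dose–response that
parameterization needs a negative slope, and the two forms are identical
under `HillSlope = −h`. We keep the positive-slope convention so that the
limits are unambiguous: 100% at `C = 0`, `R` at saturation,
`(100 + R)/2` at the IC50. `fit_hill()` uses bounded Levenberg–Marquardt
(`minpack.lm`) with a 7 × 3 multistart grid (IC50 log-spaced over three
decades around the geometric mid-dose; slopes 0.5/1/2), `R ∈ [0, 100]`,
and an honest convergence flag. Data with no downward trend are flagged
`no_inhibition` rather than fitted. Biphasic dose–response curves
(e.g. charged nanoparticles) are explicitly *not* Hill-fit;
`half_reduction_concentration()` interpolates the descending branch in
log-concentration for the ~50%-reduction dose instead.

## Barcodes

`derive_effect_barcode()` uses per-dimension two-sided t-tests — paired for
within-subject drug designs, Welch for cohort contrasts — and assigns
`trit = sign(mean difference)` where the adjusted p-value is below 0.05.
The multiple-testing correction across the seven dimensions is Holm–Šidák
by default ("none" selectable); the underlying multiple-t-test protocol in
the field is ambiguous on this point, and Holm–Šidák controls the
family-wise error without the power loss of Bonferroni. Cohort barcodes use
Welch tests rather than a two-way-ANOVA-plus-Tukey chain: at these sample
sizes the directional conclusions coincide, and the simpler test is
directly property-testable (type-I control is asserted over 1000 null
simulations). A contract-level one/two-way ANOVA with Tukey HSD remains
available as `group_compare()`, including the interaction probe for
factor synergy; its "variance heterogeneity" variant is the Welch one-way
test, reported alongside.

`add_barcodes()` is the elementwise sign of the sum. Sign saturation
(−1 + −1 → −1) is required by the composite-inhibitor identities the rule
reproduces. The operation is commutative but *not* associative: on a single trit,
`(+1 ⊕ +1) ⊕ −1 = 0` while `+1 ⊕ (+1 ⊕ −1) = +1`. The suite documents this
with a counterexample rather than pretending otherwise.

Personal barcodes classify each dimension against healthy-young reference
ranges: Gaussian mean ± 2 s.d. (~95.45% coverage). The reference interval
is closed — boundary values classify as normal — because a reference-range
test should not flag a subject sitting exactly on the healthy limit.
Gaussian fitting is on raw values by default (log-transformation is a
caller-side choice); raw fitting matches how clinical reference intervals
are typically quoted.

## BFP kinetics

The adhesion-frequency relation `P_a = 1 − exp(−m_r m_l A_c K_a)` and the
single-bond probability `λe^{−λ}/(1 − e^{−λ})`, `λ = −ln(1 − P_a)`, share
one Poisson bond-number model — the standard small-probability derivation.
At `P_a = 0.2` the single-bond probability is 89.3%, the quantitative
basis of the "~20% adhesion → ~90% single bonds" operating rule.

Lifetimes are generated from a two-pathway catch-slip off-rate
`k(F) = k_c0 e^{−F/f_c} + k_s0 e^{F/f_s}` (exponential lifetimes, mean
`1/k(F)`). Default phenotypes are calibrated through
`catch_slip_from_peak()` to the reported peaks — healthy integrin–Fg
~15 pN / ~5 s, hypertensive ~35 pN / ~10 s — with pathway force scales
(7/12 and 15/25 pN) chosen to reproduce the observable force ranges; the
rate constants are calibration, not measurement. A positive sum of
exponentials is convex, so this model cannot produce the triphasic
(slip-catch-slip) lifetime curve of healthy GPIbα–VWF bonds; the
classifier handles triphasic *curves*, but the generator only emits flat,
slip, or single-peak catch-slip phenotypes. This is a known limitation,
accepted because the two-pathway model is the simplest one reproducing the
phenotype contrasts the pipeline analyzes.

`bin_lifetimes()` uses 10-pN bins from zero by default (bin edges are not
standardized in the field; configurable) and flags bins with ≥ 50 events
reportable. `classify_force_dependence()` reads the sign pattern of
bin-to-bin changes exceeding one combined s.e.m. (configurable margin):
monotone-down = slip, single interior peak = catch-slip (peak force and
lifetime reported), down-up-down = triphasic (slip-catch-slip), no
significant change = flat. A still-rising curve at the last reportable bin
is classed catch-slip with the peak at that bin, since the slip phase lies
beyond the observable force range.

Calcium traces are normalized per the ratiometric protocol: 340/380 ratio
divided by the mean of the first 10 frames; `ΔI_max` is the post-baseline
peak minus 1, with no smoothing window (peak detection on the raw
normalized trace keeps the zero-noise round trip exact; callers can smooth
upstream if their frame rate warrants it).

## Discrimination statistics

`best_threshold()` maximizes Youden's J over midpoints between sorted
unique pooled values — "best separation" needs a criterion, and Youden's J
is the standard equal-weight choice; ties break toward higher specificity.
Being rank-based, the threshold is invariant under monotone transforms.
The sensitivity/specificity (86/85%) and consistency (81%) figures quoted
for the real cohorts are descriptors of protected clinical data: the
package validates the operations by construction on synthetic cohorts
instead of attempting to reproduce those numbers.

## Numerical choices and problem sizes

Tolerances: logistic and Hill self-fits are asserted to 0.1% on noiseless
data; the zero-noise synthesis-to-profile round trip to 1e−9 relative;
oracle equivalences (Kendall tau-b vs pair counting, F = t², lubrication
vs duct series) at machine precision, 1e−9, and 2% respectively.
Degenerate inputs fail loudly: constant traces reject growth fits, zero
control size rejects residues, zero s.d. rejects reference ranges,
`P_a = 1` rejects affinity estimation.

Stochastic checks in the suite use scaled problem sizes chosen for tight
Monte-Carlo error at desk scale: 100 repeated studies for barcode recovery
(observed ≥ 95% recovery of both the cohort and the paired-inhibitor
barcode), 100 seeds for IC50 recovery (median error ~5% at 5%
multiplicative noise, 8 doses), 1000 null simulations for type-I control
of the barcode and of the regression slope test, and 10⁴ series for the
unbiasedness of the adhesion-frequency estimator. Every generator is
deterministic given (design, seed); independent stages derive separate
sub-seeds from the base seed so that adding a stage never reshuffles
another stage's draws.

## Known limitations

- Lubrication hydrodynamics ignores inertia, 3-D end effects and
  thrombus-perturbed flow; it is an operating-point estimator, not CFD.
- The generator's distributional assumptions (log-normal noise,
  independent dimensions within cohort, logistic growth) are convenient
  idealizations; recovery results quantify the analysis, not biology.
- Triphasic bond kinetics are classified but not generated.
- Barcode addition is a saturating heuristic that reproduces the
  documented composite identities; it is not claimed to hold for arbitrary
  factor combinations.
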