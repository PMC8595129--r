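---
title: "Methods: whole-body PBPK modelling and human PK translation for nanoliposomal antisense oligonucleotides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modelling and human PK translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligopbpk)
```

`oligopbpk` implements, as one tested pipeline, the computational chain
used to characterise an intravenously dosed nanoliposomal antisense
oligodeoxynucleotide (a 20-mer polyanion, MW 6044.4 Da, targeting midkine
mRNA) in preclinical species and to project its first-in-human
pharmacokinetics: a 14-compartment whole-body PBPK model,
tissue-composition Kp prediction, noncompartmental analysis (NCA),
power-model dose-proportionality assessment, ultrafiltration
protein-binding calculation, allometric clearance scaling and a
body-surface-area (BSA) first-in-human dose. A synthetic-study generator
reproduces the designs of the monkey IV study, the rat
tissue-distribution study and the binding assay so that every stage is
testable without animal data.

## The whole-body model

The model has 14 perfused tissue compartments — lung, heart, brain,
adipose, muscle, skin, spleen, reproductive tissue, gut, liver, kidney,
yellow marrow, red marrow and a rest-of-body remainder — linked by
arterial and venous blood pools. Every tissue is well stirred and
perfusion-limited:

$$\frac{dA_t}{dt} = Q_t\left(C_{art} - \frac{C_t}{K_{p,t}}R\right),$$

in blood-concentration terms, with $R$ the blood:plasma ratio. The lung
is perfused in series by the venous pool with the full circulatory flow;
the 13 systemic tissues are perfused in parallel from the arterial pool
and drain into the venous pool. Elimination is one systemic clearance
acting on the venous *plasma* concentration, drawn from the venous
compartment. This placement makes $AUC_{0-\infty} = \mathrm{Dose}/CL$
exact for any Kp set — the structure that lets a measured in vivo
clearance drive the exposure prediction. There is no hepatic/renal
split: no prototype drug appears in excreta for this compound class, so
a single clearance referenced to the sampled matrix is the appropriate
resolution.

Design choices worth stating:

* **IV bolus as an initial condition.** A bolus at $t=0$ is placed in
  the venous pool; no injection duration is modelled. Early
  concentrations therefore reflect instantaneous mixing in the venous
  volume.
* **Flow closure.** The circulatory throughput is taken as the *sum* of
  the systemic tissue flows rather than the tabulated cardiac output.
  The two agree within 1% by validation; using the sum makes the system
  exactly mass-conservative, and simulations assert a relative
  mass-balance error below $10^{-6}$ at all times.
* **Gut is lumped.** The drug is IV-only, so no segmental absorption
  model is attached; the gastrointestinal tract is one compartment. The
  rat tissue-study generator splits it evenly into stomach and jejunum
  only so that both sampled matrices exist.
* **Solver.** `deSolve::lsoda` with rtol $10^{-8}$, atol $10^{-10}$ and
  dense reporting every 0.01 h. Tightening the tolerances tenfold moves
  AUC by less than 0.1% (asserted in the tests).

Exposure metrics use the linear-up/log-down trapezoid on the dense grid.
The log-down branch matters here: with a venous volume of a fraction of
a litre and the whole cardiac output flowing through it, the
post-bolus mixing transient has a time constant of a few thousandths of
an hour, and a linear trapezoid across it overstates AUC by nearly 1%.
The terminal extrapolation $C_{last}/\lambda$ takes $\lambda$ from a
log-linear fit over the final decade of decline of the simulated curve.

## Partition coefficients

Kp values come from the tissue-composition (Rodgers–Single family)
equations: partitioning into extracellular and intracellular water with
Henderson–Hasselbalch pH corrections, into neutral lipid and neutral
phospholipid via the neutral species, plus protein association
back-calculated from the plasma fraction unbound and scaled by a
tissue:plasma binding-protein ratio. `kp_lukacova()` dispatches by
ionization class: moderate-to-strong monoprotic bases (pKa ≥ 7) take the
electrostatic acidic-phospholipid form (association strength inferred
from red-cell partitioning via the blood:plasma ratio and hematocrit);
acids, neutrals, weak bases and permanent anions take the
protein-binding form. Both the class-dispatched entry point and the
direct equation are exported, the dispatched form being the default used
by `predict_kps()`. A permanently ionized polyanion is evaluated as the
fully ionized limit of the acid branch (effective pKa 0), which keeps
the ion's pH partitioning between intracellular water (pH 7.0) and
plasma (pH 7.4) intact. The reported Kp is referenced to total plasma
($K_p = f_{up} \cdot K_{pu}$); the unbound-referenced coefficient is
available via `reference = "unbound_plasma"`. Plasma is treated as an
effectively aqueous reference, as in the published equations, so a
hypothetical tissue that is pure water with no binding partitions at
exactly 1.

The drug descriptors of the nanoliposomal oligonucleotide are only
partly measurable: the defaults are ionization class polyanion, logP −2
(a strongly hydrophilic backbone; the lipid terms are then negligible,
so its exact value is immaterial), blood:plasma ratio 1 and human
fraction unbound 0.02 — the midpoint implied by the measured 96–99%
plasma binding. Every descriptor, and any individual Kp, can be
overridden in configuration: measured or fitted Kps always take
precedence over predictions. With these defaults the human steady-state
volume assembles to
`r round(vss_from_kps(predict_kps(physchem_profile(6044.4, "polyanion", logp = -2, fup = 0.02)), load_physiology("human_chinese_male")), 2)` L
from $V_{ss} = V_{plasma} + \sum_t K_{p,t} V_t$ — of the order of the
reported human prediction for this compound, though that reported value
is accepted only as a configuration input, never asserted.

## Physiology

The commercial software used for the original analysis does not print
its internal physiology database, so the package bundles its own
plain-text reference tables — organ volumes (unit density) and regional
blood flows compiled from the standard compendia (Brown et al. 1997;
Davies & Morris 1993) — for a 6 kg macaque, a 0.25 kg rat and a 60 kg
Chinese adult male. The 60 kg human reference is chosen because the
study's dose conversion (46 mg/kg in monkey to a 90 mg absolute human
dose at safety factor 10) is arithmetically consistent with it. Each
table validates against the structural invariants (positive volumes,
lung flow equal to cardiac output, systemic flows summing to cardiac
output within 1%, total volume at most 1.05 × body weight) and every
entry is overridable per species. The rest-of-body row closes volume
and flow balances by construction.

## Noncompartmental analysis

The NCA layer states its conventions explicitly because the original
software's defaults are not portable:

* **Terminal slope**: best adjusted-$r^2$ log-linear regression over all
  terminal windows of at least three points after (and excluding) Tmax;
  a longer window wins ties within $10^{-4}$; non-declining windows are
  rejected and the profile reported not-estimable.
* **AUC**: linear-up/log-down trapezoid; extrapolation uses the last
  *observed* concentration, $AUC_{0-\infty} = AUC_{last} +
  C_{last}/\lambda_z$, and AUMC is extrapolated consistently.
* **IV-bolus C(0)**: back-extrapolated log-linearly from the first two
  positive samples (the standard IV rule). Without it, the area between
  dosing and the first 0.08 h sample — a few percent for this rapidly
  distributing compound — would be lost, and the noise-free clearance
  recovery asserted at 2% would not hold.
* **BLQ** (LLOQ 0.18 µg/ml): pre-dose values set to 0, embedded BLQ
  treated as missing, trailing BLQ dropped.

`t_{1/2} = \ln 2/\lambda_z`, $CL = \mathrm{Dose}/AUC_{0-\infty}$,
$MRT = AUMC/AUC$ and $V_{ss} = CL \cdot MRT$ hold exactly by
construction and are asserted for every result. Per-kg doses (µg/kg)
yield per-kg CL (ml/kg/h) and Vss (ml/kg), matching the preclinical
reporting convention.

## Dose proportionality

The power model $\ln y = \alpha + \beta \ln \mathrm{dose}$ is fitted by
OLS; $\beta = 1$ indicates proportionality. The dose-normalized ratio is
$R_{dnm} = r^{\beta - 1}$ with $r$ the highest:lowest dose ratio (4 for
the 11.5/23/46 mg/kg design), its CI transformed from the slope CI, and
the classification follows the interval-inclusion rule against bounds
(0.80, 1.25): inside → proportional, disjoint → nonproportional,
otherwise inconclusive. CIs are two-sided at $\alpha = 0.10$ (90%).
When only mean ± SD summaries are available, each is first converted to
a geometric mean under a lognormal assumption,
$GM = \bar{x}/\sqrt{1 + (s/\bar{x})^2}$, and the fit uses one GM point
per dose — the point estimates are then reproducible from published
summary tables, but the CI reflects only 1 residual degree of freedom
and is not comparable to an individual-level CI (which needs all nine
animals). A 500-replicate simulation under a truly proportional truth
(3 doses × 3 subjects, lognormal noise) is asserted to give a mean
slope within 1 ± 0.05 and 86–94% CI coverage.

## Translation

Human clearance is scaled from the monkey by single-species allometry,
$CL_h = CL_a (BW_h/BW_a)^{0.8}$, the fixed exponent conventional for
macromolecules. The monkey clearance fed to scaling defaults to the mean
of the three dose groups (the study does not say which was used; every
plausible choice rounds to the same one-significant-figure prediction),
and per-dose scaling remains available. The first-in-human dose follows
the BSA rule $HED = D_a \cdot K_{m,a}/K_{m,h}$ with the standard factors
(monkey 12, human 37, bundled and overridable), multiplied by the 60 kg
reference weight and divided by the safety factor 10; the raw value is
reported alongside its nearest-10 mg rounding. The ultrafiltration
formula computes `fu% = 100 · C_buffer/C_plasma`; because binding
studies report the complement, both fu% and bound% = 100 − fu% are
returned, explicitly labelled.

## The synthetic-study generator

The generator emulates the study designs, not any particular observed
dataset:

* **Monkey IV study**: 3 dose levels (11.5, 23, 46 mg/kg) × 3 animals,
  sampling at 0.08–6 h, plasma plus all-BLQ urine and feces. Truth
  per-kg clearance defaults to 100 ml/kg/h (the magnitude observed for
  this compound class); subject clearance and a common Kp scale are
  lognormal with 15% CV, residual error proportional lognormal with 10%
  CV — a standard PK variability structure, chosen once, since no
  variance components are published to copy.
* **Rat tissue study**: single 25 mg/kg dose, kills at 0.17/0.5/2/6 h,
  nine tissues plus plasma, homogenate dilution (1 g + 10 ml, factor 11)
  applied and inverted in reporting, and percent of injected dose per
  gram. The truth Kps are configuration values chosen to honour the
  observed tissue AUC rank order (kidney > spleen > liver > fat >
  jejunum > stomach > lung > heart > muscle > plasma) — they are design
  fixtures, not estimates.
* **Binding study**: buffer/plasma chamber pairs at the 0.25/2.5/25
  µg/ml QC levels consistent with per-matrix true fractions unbound plus
  multiplicative noise.

The default seed is 20211103 and every generated dataset carries its
seed as an attribute; identical seeds reproduce byte-identical data.
What the generator deliberately does *not* emulate: the saturable,
dose-dependent tissue uptake that makes the real kinetics nonlinear
(the truth model is linear, so proportionality holds by construction),
assay measurement mechanics beyond a proportional error and an LLOQ cut,
and any rat plasma PK parameters (never tabulated; configuration only).
Passing tests therefore demonstrate that the pipeline recovers the
parameters of a *linear* truth under realistic designs and noise — not
that the real compound is linear.

## Problem sizes and runtime choices

The test suite simulates the 17-state system for horizons of 6–96 h at
a 0.01 h reporting step, runs 500 power-model replicates for the
calibration check, and 50 randomized Kp draws for the non-negativity
property — all chosen to exercise the invariants at full fidelity while
keeping a complete run in the tens of seconds on one core.

## Known limitations

Perfusion-limited tissues only (no permeability limitation, transporter
effects or lysosomal trapping of the liposomal carrier); the
encapsulated and free drug are not distinguished; no oral absorption
machinery; no target-mediated disposition or saturable uptake, so the
observed dose-dependence of half-life is outside the model's reach; no
PBPK parameter estimation — clearance is an input, not a fit. Predicted
peak concentrations immediately after a bolus depend on the venous
mixing convention and should not be over-interpreted.
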