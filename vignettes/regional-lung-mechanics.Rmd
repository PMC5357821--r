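---
title: "Regional lung mechanics from functional respiratory imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lung mechanics from functional respiratory imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungfri)
library(dplyr)
```

## The problem

Mechanical ventilation is monitored almost exclusively through whole-lung
quantities — airway pressures, tidal volume, respiratory-system compliance.
Ventilator-associated lung injury, however, is driven by *regional* tissue
strain: a lobe with a small resting volume receiving a large share of the
tidal volume is strained far more than whole-lung numbers suggest.
Functional respiratory imaging (FRI) addresses this by combining
CT-segmented lobar volumes and airway geometry with a flow computation, so
that strain, resistance, elastance and the expiratory time constant can be
attributed to individual lobes.

`lungfri` implements that computation chain for the seven-lobed pig lung
(right anterior, caudal, diaphragmatic and internal lobes; left anterior,
caudal and diaphragmatic: RAL, RCL, RDL, RIL, LAL, LCL, LDL), together
with the statistical layer used to compare lobes and PEEP levels, and a
synthetic cohort generator that stands in for CT-derived data so every
stage is testable end to end.

## The mechanics model

For each lobe $L$ with end-expiratory and end-inspiratory volumes
$\mathrm{EELV}_L$ and $\mathrm{EILV}_L$:

* **Strain**: $\varepsilon_L = (\mathrm{EILV}_L - \mathrm{EELV}_L)/\mathrm{EELV}_L$,
  with EELV inclusive of the PEEP-recruited volume. The whole-lung value
  uses the summed volumes and is algebraically the EELV-weighted mean of
  the lobar strains.
* **Expiratory flow**: total flow is the exhaled volume over the deflation
  time $T_E$; each lobe receives the fraction given by its share of the
  exhaled volume. With a square-wave inspiratory flow $\dot V_I$ the
  deflation window is $T_E = 60/f_b - V_T/\dot V_I$ (4.68 s at the default
  settings of 6 mL/kg, 12 breaths/min, 45 L/min).
* **Resistance**: the lobar flows are imposed as inlet boundary conditions
  at the terminal bronchi and the trachea is a pressure outlet at PEEP.
  The steady laminar network solution gives each region's pressure drop;
  $R_L = \Delta P_L / Q_L$.
* **Elastance**: $E_L = \Delta P_{trach} / (\mathrm{EILV}_L -
  \mathrm{EELV}_L)$, where $\Delta P_{trach}$ is the tracheal pressure
  drop over deflation — a single scalar per pig and PEEP. A consequence
  exposed as a tested invariant is the parallel-compartment identity
  $\sum_L 1/E_L = 1/E_{RS}$.
* **Time constant**: $\tau_{E,L} = R_L / E_L$.

### The reduced-order flow solver

The original FRI workflow solves the 3D Navier–Stokes equations on a
segmented airway geometry. This package deliberately replaces that with a
one-dimensional laminar network: every airway segment is a straight tube
with Hagen–Poiseuille resistance $8\mu L/(\pi r^4)$, segment flows are
sums of descendant terminal flows, and junction pressures accumulate
$R\,Q$ drops from the tracheal outlet towards the periphery. The regional
quantities the analysis consumes (per-region pressure drop, resistance)
are zero-dimensional summaries of the 3D field, and the laminar steady
regime is the same; a desk-scale 1D solve preserves exactly the quantities
of interest. The solver is verified against an independent brute-force
path-summation oracle to $10^{-9}$ relative on hundreds of random trees.

Two definitional choices were genuinely open:

* **A lobar region has many inlets.** We define the lobar pressure drop
  as the *flow-weighted* mean pressure over the lobe's terminal entries
  minus the pressure at its junction to the central airways; flow
  weighting is the energy-consistent scalar summary. The central drop and
  the whole-system resistance
  $R_{RS} = (\bar P_{term} - P_{outlet})/Q_{tot}$ are defined analogously.
* **Lobar R excludes the central share.** Reported lobar resistance covers
  only the lobe's own region; the central airway resistance is reported
  separately rather than apportioned, since any apportioning rule would be
  arbitrary.

Units are fixed at cmH2O, L and s at every public interface (PEEP is set
in cmH2O clinically); geometry is in SI and the single conversion constant
(1 cmH2O = 98.0665 Pa) lives in one place.

## The deflation simulator

`simulate_deflation()` integrates parallel lobar RC compartments emptying
through a shared central resistance into a PEEP source:
$\dot V_L = -(V_L/C_L + \mathrm{PEEP} - P_{aw})/R_L$, with the
airway-opening pressure $P_{aw}$ solved algebraically at each step from
the flow balance across the central resistance (one scalar equation, so
the system never becomes stiff through the coupling). Compliances are
linear, airways rigid, inertance neglected — the quasi-static laminar
framing of the mechanics model. With zero central resistance each
compartment decays as $e^{-t/R_LC_L}$, which links the FRI quotient
$\tau_E = R/E$ to an observable: the log-volume slope of a simulated
pneumotach trace recovers $RC$ within 1%, a cross-module closed-form check
in the test suite. The default integrator is adaptive (`lsoda`, relative
tolerance $10^{-8}$); a fixed-step RK4 mode is kept for reproducibility
experiments and refuses steps larger than a fifth of the smallest time
constant.

## The synthetic cohort generator

No imaging data are distributed with the package; the generator emulates
the *statistical structure* of an ex-vivo porcine study: 5 pigs × 3 PEEP
levels (0/5/10 cmH2O) × 7 lobes, ventilated at 6 mL/kg, 12 breaths/min,
45 L/min square-wave inspiratory flow. Mechanisms, with defaults chosen
once to be physiologically plausible and to reproduce the directional
findings the statistical layer is meant to detect:

* **Volumes.** Lobar resting volume is `baseline + C_L × PEEP` (linear
  EELV–PEEP relation); baseline whole-lung EELV is 1.0 L for a 40 kg
  animal (cadaveric lungs without a chest wall rest well below in-vivo
  FRC) split over lobes by anatomically plausible fractions. Tidal volume
  distributes across lobes in proportion to lobar compliance
  (quasi-static parallel compartments).
* **Elastance step.** Whole-lung compliance is 0.060 L/cmH2O at PEEP 0
  and 5 and steps down to 0.045 at PEEP 10 — the simplest mechanism
  producing elevated elastance at high PEEP (the upper, flatter part of
  the pressure–volume curve).
* **Airway dilation.** Airway radii carry a PEEP-dependent multiplier, so
  resistance falls as PEEP rises. The left anterior lobe is generated
  narrowed (×0.75), giving it the highest resistance and time constant.
* **Tau–strain coupling.** Per-lobe calibre noise (one log-normal draw
  per pig/PEEP/lobe) controls how tightly a lobe's $\tau_E$ couples to
  its strain across PEEP. RAL and LCL are generated with tight coupling:
  almost no calibre noise, and a radius–PEEP profile solved analytically
  so the noise-free $\tau_E$ is collinear with strain across the three
  PEEP levels (for tight lobes the three-point profile is
  {1, 1.239, 1.350}). LDL and RDL have flat profiles and large calibre
  noise (weak coupling); the remaining lobes sit between. The whole-lung
  time constant is additionally decorrelated from whole-lung strain by
  per-pig central-airway calibre variability (log-SD 0.30), representing
  inter-animal variation in trachea/main-bronchus calibre relative to the
  fixed endotracheal tube: the central share of $R_{RS}$ is large, so
  whole-lung $\tau_E$ varies mostly between animals while whole-lung
  strain does not.
* **Noise.** Multiplicative log-normal noise: a per-pig size factor
  (log-SD 0.05) scales resting volumes, compliances and — because tidal
  volume is dosed per kg — the delivered VT, leaving strain
  size-invariant while elastance and $\tau_E$ carry a recoverable
  random-pig component; independent per-cell residuals (log-SD 0.03) on
  EELV and on the tidal increment keep volumes positive.
* **Determinism.** One global seed with documented per-pig substreams:
  regenerating with more pigs leaves earlier pigs' draws untouched, and
  identical (config, seed) reproduce the cohort bit for bit.
* **Airway trees.** Trachea (lumen set by the 9 mm endotracheal tube)
  feeding two main bronchi, each feeding complete binary lobar subtrees
  of configurable depth (default 3 generations; the anatomical depth of
  "terminal bronchi" after segmentation is not a quantity the model pins
  down, so it is a free parameter). Radii follow a per-generation
  homothety ratio of 0.78 with small per-segment jitter.

What the generator does **not** emulate: CT acquisition noise,
segmentation error, recruitment/derecruitment dynamics, nonlinear
compliance, gravitational gradients. Tests passing on synthetic cohorts
therefore demonstrate that the computation chain and the statistics
behave correctly under the assumed mechanisms — not that those mechanisms
exhaust real lungs. Absolute resistance values are airway-only laminar
resistances and sit well below physiological total respiratory
resistance (which includes tissue and turbulent components); the package
is about regional *contrasts*, which the laminar model preserves.

## The statistical layer

Each mechanics response (strain, R, E, $\tau_E$) is modelled as
`response ~ lobe * PEEP + (1 | pig)` by REML, whole-lung rows separately
as `response ~ PEEP + (1 | pig)`. Choices that were open, and why:

* **PEEP as a categorical factor** — the scientific questions are
  pairwise comparisons of discrete PEEP settings, which requires factor
  coding rather than a linear trend.
* **Type-III F-tests with Satterthwaite denominator df** — the common
  default for small balanced animal designs; documented so results are
  exactly reproducible. Kenward–Roger is deliberately out of scope.
* **Tukey–Kramer on least-squares means** (studentized-range adjustment
  at Satterthwaite df) for all pairwise level contrasts.
* **Singular fits are flagged, not fatal**: a variance component at the
  boundary (or a degenerate design, e.g. one pig) yields a result object
  with the component zeroed and a `flagged` marker, so simulation sweeps
  and pipelines keep running.
* **Tau–strain coupling** is assessed per lobe (and for the total lung)
  with `tau ~ strain + (1 | pig)`; the Nakagawa–Schielzeth marginal
  pseudo-R², $\sigma^2_f/(\sigma^2_f + \sigma^2_{pig} + \sigma^2_{res})$
  with $\sigma^2_f$ the variance of the fixed-effect predictor over the
  data, measures the share of $\tau_E$ variance explained by strain.
  The eight strain-term p-values are controlled by the Benjamini–Hochberg
  step-up procedure, implemented directly because the attained step-up
  critical level $i^*\alpha/m$ is part of the reported output (the
  standard `p.adjust` returns only adjusted p-values; it serves as the
  independent oracle in the tests).

## Numerical choices and degenerate inputs

* Solver tolerances are not iterative: the network solve is a direct
  two-pass accumulation, exact to rounding; the oracle-equivalence test
  bounds accumulated rounding at $10^{-9}$ relative on 63-segment trees.
* Zero-flow lobes make $R = \Delta P/Q$ undefined; rows are emitted with
  `NA` resistance and time constant plus a warning, and model fits drop
  them, rather than fabricating 0/0.
* Ties in the BH step-up resolve by taking the largest passing rank, the
  standard step-up convention.
* Trees are validated before any solve; every violation names the
  segments involved.
* JSON airway-tree serialization uses 17 significant digits so geometry
  round-trips bit-exactly.

## Problem sizes used in the shipped checks

The package's own verification runs at deliberately modest sizes, chosen
as the smallest that make the statistical assertions sharp: 200 random
trees (≤ 63 segments) for oracle equivalence; a 5 × 5 log-grid for the
deflation closed form; 100 replicate cohorts for variance-component
recovery; 500 null replicates for the type-I error of the PEEP test
(band 0.02–0.09 at nominal 0.05); 100 replicates for power; and 10 seeds
for the directional summary of the calibrated cohort.

## Known limitations

* The laminar Poiseuille closure ignores inertial and Pedley-type
  entrance corrections; at the default flows (Reynolds numbers well below
  the turbulent range in sub-lobar airways, modest in the trachea) this
  biases central resistance low but preserves regional contrast.
* The elastance driving pressure is the end-inspiratory recoil above
  PEEP, applied identically to every lobe of a cell — the only reading
  that makes lobar elastance computable from a single tracheal scalar;
  its consequence (reciprocal additivity) is exposed as an invariant
  rather than hidden.
* The deflation window is operationalized as cycle time minus
  square-wave inspiratory time; if deflation effectively ends earlier
  (flow reaching zero), true mean expiratory flows would be higher by a
  common factor, rescaling resistances but not their contrasts.
* With five animals, pig-level variance components are estimated on ~4
  denominator degrees of freedom; single-study estimates of that
  component are intrinsically noisy (roughly a factor-of-two band on the
  SD), which is why the recovery checks run over replicates.

## A worked run

```{r example, eval = FALSE}
co   <- generate_cohort(cohort_config(), seed = 1)
mech <- compute_fri_table(co)
rep  <- run_statistics(mech)
print(rep)
plot_mechanics(mech, "tau", by = "lobe")
```
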