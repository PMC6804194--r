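---
title: "Modelling proanthocyanidin adsorption and desorption on grape cell wall material"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling proanthocyanidin adsorption and desorption on grape cell wall material}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasorption)
```

## The system and the model

During red wine maceration, proanthocyanidins (PA; condensed tannins
extracted from grape skins and seeds) adsorb onto the insoluble cell wall
material (CWM) of the grape solids, removing them from the wine. The extent
of that adsorption depends on temperature and ethanol concentration, both of
which change over a fermentation. This package implements a quantitative
treatment of the phenomenon as a single-layer (Langmuir) adsorption
equilibrium:

$$q_{PA} = \frac{C_{PA}\,K_{eq}\,S_{CWM}}{1 + C_{PA}\,K_{eq}}$$

where $q_{PA}$ is the adsorbed PA per mass of CWM (mg PA per mg CWM),
$C_{PA}$ the dissolved PA concentration at equilibrium (mg/L), $K_{eq}$ the
equilibrium constant (L/mg) and $S_{CWM}$ the saturation capacity of the CWM
(mg/mg). All PA amounts are in catechin units (C.U.), i.e. expressed
against a (+)-catechin calibration of the 510 nm iron-reactive phenolics
assay.

$K_{eq}$ and $S_{CWM}$ are not constants of the material alone: both depend
on temperature and ethanol. They are modelled as rational surfaces in
absolute temperature $T$ (Kelvin) and ethanol $E$ (% v/v),

$$f(T, E) = \frac{n_0 + n_T T + n_E E}{d_0 + d_T T + d_E E + d_{TE}\,T E},$$

calibrated on batch adsorption experiments spanning 15–35 °C and 0–15 %
ethanol at 500–1500 mg/L PA. Users give temperatures in °C everywhere; the
conversion to Kelvin is internal, because the surfaces are written in
Kelvin while bench work is reported in Celsius.

### The coefficient transcription decision

The published constants of the two surfaces suffer from a typesetting
ambiguity in the superscript exponent signs. Taken literally, the printed
constants make the saturation surface collapse to $S_{CWM}(T, 0) = 1/T$
(about 0.0035 mg/mg at 15 °C) — two orders of magnitude below the
adsorption capacities actually measured on skin CWM (0.2–0.35 mg/mg), and
unable to reproduce the published winemaking extrapolation built on the
same model. Restoring two exponent signs (the temperature coefficient of
the $K_{eq}$ numerator and the constant of the $S_{CWM}$ numerator) yields
surfaces that are strictly positive over the calibrated envelope and
reproduce all four headline numbers of the winemaking extrapolation within
8 %. The package therefore ships two coefficient sets:

* `surface_coefficients("default")` — the repaired transcription, used
  everywhere by default;
* `surface_coefficients("printed")` — the constants exactly as typeset,
  retained for traceability.

Both sets, and any user-supplied correction, can be swapped in through the
`coefficients` argument of every modelling function or the
`model.coefficients` config block. Note that with the default set the
equilibrium constant is very large over the whole envelope, so the isotherm
operates near saturation and the behaviour of the system is governed almost
entirely by $S_{CWM}(T, E)$; the $K_{eq}$ denominator also has a pole just
outside the calibrated corner (about 15.2 % ethanol at 35 °C), one reason
evaluation outside the envelope is flagged as extrapolation rather than
forbidden.

## The batch equilibrium solve

A closed vessel with liquid volume $V$, CWM mass $m$ and total PA mass
$M$ satisfies the mass balance $C V + q m = M$. Substituting the isotherm
gives a quadratic in $C$,

$$V K C^2 + (V + m K S - K M)\,C - M = 0,$$

whose root product is $-M/(V K) \le 0$: exactly one root is non-negative,
and it always lies in $[0, M/V]$. The solver selects that root (with the
numerically stable form of the quadratic formula to avoid cancellation),
asserts the other root is inadmissible, and reports the mass-balance
residual of the returned state. Degenerate inputs are handled explicitly:
zero CWM returns the trivial dissolved state, zero volume with PA present
is an error. A bisection solver on the mass-balance residual serves as an
independent oracle in the test suite (1000 random systems, agreement to
relative 1e-9).

## The temperature-ramp desorption experiment

The bench experiment this package emulates equilibrates 4.5 mL of
1500 mg/L PA solution with 10 mg of CWM at 15 °C (720 min), then raises
the temperature to 22.5, 30 and 35 °C (120 min holds), sampling the
supernatant at each step. `simulate_ramp()` treats each step as a full
re-equilibration — the analysis of the bench data itself treats the
sampled states as equilibria, and the hold times are carried only as
metadata. Percent desorption at step $k$ is
$100\,(A_1 - A_k)/A_1$ with $A_1$ the 15 °C adsorbed mass, the maximum
recoverable pool; negative values (net further adsorption) are reported,
not clipped.

Three reversibility assumptions are available:

* `equilibrium` — every step is an independent batch solve; this is the
  fully reversible model assumption.
* `empirical` — measured per-step desorption fractions are imposed on the
  step-1 adsorbed mass. `reference_desorption()` ships the benchmark
  triplicate means (e.g. 26.73, 37.36 and 47.96 % at 15 % ethanol), and
  the fractions round-trip exactly through the percent-desorption series.
* `partial` — a fraction $\varphi$ of the step-1 adsorbed pool is treated
  as irreversibly bound. A literal "re-equilibrate only the reversible
  pool" construction cannot honour the fully irreversible limit at
  constant temperature (blocking sites changes the step-1 fixed point), so
  the implementation applies $\varphi A_1$ as a floor on the equilibrium
  adsorbed mass. This keeps the two anchor cases exact — $\varphi = 0$
  coincides with `equilibrium` and $\varphi = 1$ yields zero desorption at
  any temperature — and interpolates monotonically between them.

Supernatant withdrawal (125 µL per sampling on the bench, about 2.8 % of
the volume per step) is ignored by default but can be enabled with
`withdrawal_uL`, which depletes both the volume and the dissolved PA
between steps; its effect at the bench scale is well inside assay noise,
which is why ignoring it is the default.

## The quantification chain

Concentrations come from the ferric chloride assay: 75 µL of sample in
800 µL of buffer are read at 510 nm (background, 875 µL total), then
125 µL of reagent are added and the mixture is read again (1000 µL total).
The background read is taken at a different total volume than the final
read, so `concentration_from_absorbance()` rescales it by 875/1000 before
subtraction — the volume-consistent choice — and maps cuvette
concentration back to sample concentration with the 1000/75 dilution
factor. Both factors are fields of `assay_calibration()` and can be
changed. Negative concentrations (noise near blank) floor at zero with a
warning. Adsorbed amounts use the control-trial difference method:
$q = (\bar{C}_{control} - C_{trial})\,V/m$, with CWM-free control
triplicates averaged per step.

## Statistics

`summarize_desorption()` reports arithmetic means and sample standard
deviations ($n-1$) per (ethanol, temperature) cell; a single replicate has
no dispersion estimate. `anova_letters()` produces a compact letter
display from one-way ANOVA at $\alpha = 0.05$ followed by Tukey HSD when
the overall test is significant. The bench study's letters came from
spreadsheet ANOVA with an unstated multiple-comparison step; Tukey HSD is
the field's standard generator of letter displays and is used here as a
deliberate substitution, so exact letter agreement with the original
tables is not expected. When every group has zero within-group variance
the F statistic is undefined and letters are assigned by exact equality.
`model_error()` compares observed isotherm points to the model per
condition: mean absolute error, mean percent error with the *observed* q
as denominator (matching "error between the data and the model"), and a
separately reported signed bias so "overestimates/underestimates"
statements are reproducible.

## Composition metrics

Phloroglucinolysis converts extension subunits into phloroglucinol
adducts and releases terminal subunits free, so the mean degree of
polymerization is the total-to-terminal mole ratio. Percent galloylation
counts epicatechin-gallate subunits and percent gallo units counts
epigallocatechin subunits, both as molar shares of the whole pool. The
average molecular weight is mDP times the mole-weighted free flavan-3-ol
mass; interflavan-bond and phloroglucinol-adduct mass corrections are
deliberately not applied (no correction convention is fixed by the source
methodology; supply a modified `subunit_mw_table()` to change it).

GPC traces are mapped through a monotone size calibration to (molar mass,
mass) pairs and accumulated from low to high molar mass, so the molar
mass at 90 % cumulative mass characterises the high-mass tail — the
convention under which preferential loss of large PA shows up as a drop
in that quantile. Quantiles are linearly interpolated between samples;
zero-signal samples are dropped first so that a point mass is not smeared
across a grid cell.

## The synthetic-data generator

`generate_measurements()` emulates the statistical structure of the bench
experiment: triplicate CWM-free controls (constant dissolved truth) and
triplicate trials (per-step ramp equilibria), converted to absorbance
pairs by inverting the assay calibration so the quantification chain is
an exact round trip at zero noise. Noise is multiplicative Gaussian on
concentration — replicate scatter in the benchmark table grows with the
mean — with CV 0.03 and three replicates as defaults, sized to the
benchmark standard deviations (CV roughly 1–10 %); placement on
absorbance instead is available. All generators are pure functions of
their parameters and seed and restore the caller's RNG state.

What the generator does *not* emulate: instrument drift, carryover,
between-day calibration changes, background phenolics varying across
samples, or any adsorption kinetics. Passing recovery tests therefore
demonstrates the correctness of the estimation chain under the stated
noise model, not robustness to every failure mode of real assay data.

## Problem sizes and numerical choices

The validation suite uses problem sizes chosen to make the statistical
assertions sharp while staying quick to run: 1000 random systems for the
solver-versus-bisection oracle, 100 seeds for noisy isotherm-fit recovery
(within 10 % at CV 2 %, 24 points), 500 seeds for the end-to-end
synthetic recovery (bias under 0.5 percentage points at CV 3 %), and 1000
null simulations for the letter-display type-I error (5 % ± 2 %). The
end-to-end recovery is run at 0 % ethanol, where the control-trial
concentration contrast is largest relative to noise; ratio-of-noisy-means
bias grows quadratically in the relative noise of the baseline difference
and would dominate at the weakest-contrast condition. Singular surface
denominators are detected at 1e-12; quadratic roots are computed in the
cancellation-free form; fits run under positivity bounds with
Levenberg-Marquardt.

## Limitations

The parameter surfaces are empirical rational fits with no thermodynamic
interpretation, valid only on 15–35 °C × 0–15 % ethanol; the default
transcription is validated against the published extrapolation rather
than against the original fitting data, which are not available in
numeric form. The equilibrium ramp mode underpredicts observed
temperature-driven desorption (the bench study's central finding is
precisely that the reversible model misses part of the temperature
effect); the empirical and partial modes exist to bracket that behaviour.
A-type proanthocyanidins, adsorption kinetics, and fermentor-scale
effects (cap temperature gradients, maceration management) are out of
scope.
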