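---
title: "Models and methods behind quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

quenchbind implements the complete analysis chain of a fluorescence
titration binding study: a protein solution (the worked system is human
serum albumin, HSA, at 1 µM) is titrated with a ligand (here six PFAS
congeners, 0–18 µM in 3 µM steps), emission spectra are recorded at several
temperatures, and a cascade of small linear models turns the intensity decay
into mechanistic and thermodynamic statements. This vignette records the
models, the assumptions they lean on, the tunable parameters, and the design
choices that were genuinely open.

## Intensity extraction

Everything downstream consumes a single intensity F per titration point.
Two policies are offered because real spectra both quench *and* shift:

* `fixed_reference` (default): F is read at one emission wavelength,
  defaulting to the peak of the ligand-free (F0) spectrum. This is the
  textbook Stern–Volmer convention — the theory is written for intensity at
  a fixed wavelength.
* `per_spectrum_max`: F is each spectrum's maximum, tracking a drifting
  band. Useful when the complex's emission blue-shifts appreciably, as
  albumin's tryptophan band does on PFAS binding (peak moving from
  337 nm toward ~317 nm at high bound fraction).

With a shifting band the two policies answer slightly different questions:
the fixed-wavelength intensity mixes true quenching with the chromatic
shift, while the peak maximum isolates the band height. The package's
identity tests exploit this deliberately — machine-precision round trips
against the simulator use either a shift-free configuration at a fixed
reference, or the peak-height policy (accurate to the wavelength grid,
about 2e-4 relative at 1 nm spacing).

When matched absorbances at the excitation and emission wavelengths are
present, the inner-filter correction F_corr = F_obs·10^((A_ex+A_em)/2) is
applied before any extraction; when they are absent the correction is
skipped, mirroring practice where UV–vis data exist only for some series.

## Quenching mechanism

The Stern–Volmer law F0/F = 1 + K_SV[Q] is fitted by unweighted ordinary
least squares (no weighting scheme is standard for 7-point titrations).
The ligand-free point enters the regression as the (0, 1) anchor: the law
forces the intercept toward one and including the origin-region point
stabilises the three smallest designs the validators allow. K_q = K_SV/τ0
uses the unquenched lifetime τ0 = 1e-8 s, the canonical biopolymer value;
both τ0 and the diffusion limit are configuration values, not constants
buried in code.

The mechanism call combines two classical diagnostics:

| K_SV trend with T | max K_q vs 2e10 L/mol/s | call |
|---|---|---|
| strictly decreasing | any | static |
| strictly increasing | above | mixed |
| strictly increasing | at/below | dynamic |
| flat / non-monotonic | above | static |
| flat / non-monotonic | at/below | indeterminate |

"Flat" means all successive differences within a relative tolerance of
1e-6 — real data never triggers it, but synthetic edge cases (and exact
forward-model data) do, and the classifier must be total. The rationale
for the table: falling K_SV can only come from complex dissociation at
higher temperature (static); rising K_SV is the collisional signature, but
no purely collisional process can exceed the diffusion-controlled rate, so
a super-diffusion K_q forces at least a static component.

## Binding constant and site number

The double-logarithmic (modified Stern–Volmer) model
log10((F0−F)/F) = log10(K_b) + n·log10[Q] is fitted over the nonzero
concentrations only (log 0 is undefined; the zero point supplies F0).
Base-10 logarithms are used throughout, so the intercept is log10 K_b
directly. Two deliberate strictures:

* [Q] is the *total added* ligand concentration. The underlying relation is
  conventionally used with nominal titration concentrations; a free-ligand
  mass balance would change both the fit and the simulator, and is out of
  scope. This is a known approximation at ligand:protein ratios where
  binding depletes the free pool.
* Points with F ≥ F0 at nonzero concentration raise an error rather than
  being clipped: (F0−F)/F ≤ 0 has no logarithm and indicates either no
  quenching or a data problem, which should surface loudly.

## Thermodynamics and force classification

Van't Hoff: OLS of ln K_b on 1/T gives ΔH = −R·slope and ΔS = R·intercept
(R = 8.314 J/mol/K), assuming ΔH constant over the 12 K span — a
three-point fit cannot support curvature anyway, which is why no
heat-capacity term is offered. Per-temperature Gibbs energies are reported
as ΔG = −RT·ln K_b from the binding constants directly, *not* as ΔH − TΔS:
for the bundled reference table the former reproduces the tabulated ΔG
column and the latter does not, a discrepancy inherited from the source
data and documented in the reference-table help.

Force classification follows the (ΔH, ΔS) sign rules: (+,+) hydrophobic,
(−,−) hydrogen bond / van der Waals, ΔH ≈ 0 (or < 0) with ΔS > 0
electrostatic. "Close to zero" needs a number; none is standard, so the
band is ±10 kJ/mol and configurable (`near_zero_kj_mol`). The near-zero
band takes precedence over the hydrophobic rule so that a small positive
ΔH with positive ΔS reads as electrostatic.

## Competition and site assignment

The displacement ratio is φ = (K_b − K_b′)/K_b × 100. The factor is ×100
(a percentage); a ×10 variant circulates in print but is inconsistent with
the percentages those same tables report, so the package implements the
percentage form. Negative φ (apparent enhancement) is allowed and flagged
with a warning rather than an error — probe-induced conformational change
can genuinely increase affinity.

The default probe map is warfarin → IIA, ibuprofen → IIIA, lidocaine → IB.
Lidocaine's subdomain is reported inconsistently in the literature (IB vs
IIB); the default follows the usage in the results being mirrored, and the
map is plain configuration. The winner is the maximum-φ probe, ties broken
alphabetically (deterministic output matters more than any tie semantics;
ties are degenerate inputs). `dominance_pct = 80` separates "this probe
clearly owns the site" from a merely-largest φ; the bundled warfarin values
are all ≥ 93%, so the default is conservative without being vacuous.

## Energetics and correlation

MM/GBSA rows are validated against ΔG_bind = ΔE_VDW + ΔE_ELE + ΔG_GB +
ΔG_SA with a tolerance of 0.01 kcal/mol (+1e-9 guard), matching
two-decimal tables; a missing total is filled from the component sum, and
an inconsistent printed total is kept but flagged with its residual.
Ranking is ascending in ΔG_bind with alphabetical ties.

Correlations are plain Pearson on the *raw* metric values, not log K_b:
raw values reproduce the reference study's quoted coefficients, so raw is
the default (log-transforming is a caller-side `mutate()` away). Both the
signed matrix and |r| are kept, because inverse affinity–energy
relationships are conventionally quoted by magnitude. Metrics with fewer
than two distinct values have no defined correlation and are reported as
`NA`, never coerced to zero. The package computes no significance tests:
with six compounds a p-value would be theatre, and the source analyses
report none.

## The simulator

`simulate_titration()` composes, in order: the static-quenching signal
F(Q) = f0/(1 + K_b·Qⁿ) (the exact algebraic inverse of the double-log
fit), a Gaussian emission band of that height whose centre moves from the
free peak (337 nm) to the bound peak (317 nm) in proportion to the bound
fraction b(Q) = K_b·Qⁿ/(1 + K_b·Qⁿ), optional inner-filter attenuation by
10^−((A_ex+A_em)/2) (which `correct_inner_filter()` inverts exactly), and
finally multiplicative Gaussian noise I·(1 + ε), ε ~ N(0, sd). A
`stern_volmer` mode substitutes F0/F = 1 + K_SV·Q for quenching-module
tests. Temperature dependence comes from ln K_b = −ΔH/(RT) + ΔS/R when
(ΔH, ΔS) are configured.

Defaults mirror the worked assay: 1 µM protein, 275 nm excitation,
0/3/6/9/12/15/18 µM ligand, 298/304/310 K, emission 275–500 nm at 1 nm,
f0 = 1000 (arbitrary units), band sd 25 nm (≈ 60 nm FWHM, typical of a
tryptophan band), noise sd 1% — a realistic photodetector figure and the
level at which the recovery bands are stated. Noise is multiplicative
because detector error scales with signal. Seeding uses one substream per
(seed, temperature); a fixed seed is bit-reproducible, and the global RNG
stream is left untouched.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: free-ligand depletion, excited-state
kinetics (FRET, lifetime heterogeneity), Rayleigh/Raman scatter, baseline
drift, instrument response, and any deviation of a real binding isotherm
from the 1:n Hill-like form. Recovery tests certify the estimators against
their own generating model, not the model against nature.

## Numerical choices

* Peak location is grid argmax by default; three-point parabolic
  refinement is opt-in (`refine = TRUE`) so default results are
  bit-reproducible on the instrument grid. Shift classification uses a
  ±0.5 nm tolerance to absorb grid resolution.
* Perfect fits (noiseless forward data) would make `summary.lm` warn and
  return an ill-defined r²; the fitters suppress the warning and report
  r² = 1 when the response variance is below 1e-30.
* The noiseless (K_b, n) recovery sweep in the tests uses a
  conditioning-aware tolerance, max(1e-9, 50·eps/min-occupancy): at the
  weak-binding, high-n corner (K_b = 1e2, n = 2.5) the bound fraction is
  ~1e-12 and the (F0 − F) subtraction cannot do better in doubles. The
  central, physically realistic cases hold at 1e-9 or tighter.
* Fixture CSVs serialise numerics at 15 significant digits with the ground
  truth in a commented header; write-then-read round-trips to at least 12
  significant digits.
* Stochastic test sizes: 500 single-temperature replicates for the K_b
  recovery band and 100 three-temperature studies for the end-to-end
  (IFE → affinity → Van't Hoff) band — enough for stable medians while
  keeping the default suite a few minutes long.

## Known limitations

Three-point Van't Hoff fits yield OLS standard errors only — no confidence
intervals worth the name. The site-number n is an apparent cooperativity
parameter, not a count of crystallographic sites. Competition analysis
assumes the probe's subdomain assignment is correct and exclusive.
EEM handling is peak-picking near seeded positions only; scatter removal
and full chemometric decomposition are out of scope, as are vendor
instrument formats and CD deconvolution.
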