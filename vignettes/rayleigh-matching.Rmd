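---
title: "Modeling Rayleigh matches on LED anomaloscopes"
author: "RayleighMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Rayleigh matches on LED anomaloscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RayleighMatch)
```

## The model

An anomaloscope presents two fields: a mixture of a red and a green
primary, controlled by a single setting, and an amber reference with its
own intensity control. An observer adjusts the mixture until the two
fields look alike. In the Rayleigh spectral region only two cone classes
are appreciably sensitive (S cones are constructed by the package but
excluded from every match computation), so for an observer with cone
sensitivities $a(\lambda_w)$ and $b(\lambda_w)$ the match is the mixture
setting $\lambda^\ast$ at which

$$
\frac{\int P_{\mathrm{mix}}(\lambda^\ast, \lambda_w)\,a(\lambda_w)\,d\lambda_w}
     {\int P_{\mathrm{mix}}(\lambda^\ast, \lambda_w)\,b(\lambda_w)\,d\lambda_w}
=
\frac{\int P_{\mathrm{amber}}(\lambda_w)\,a(\lambda_w)\,d\lambda_w}
     {\int P_{\mathrm{amber}}(\lambda_w)\,b(\lambda_w)\,d\lambda_w},
$$

the intersection of the mixture's cone-excitation ratio curve with the
amber field's horizontal line. The right-hand side is invariant to the
amber intensity, because intensity scales both integrals equally; this
invariance is asserted by the test suite to $10^{-9}$ in $\lambda^\ast$.
All spectra are handled in energy units; excitations are plain inner
products (sum of products times the grid step) on a shared 390–780 nm,
1 nm grid. No quantal conversion is applied, since the fundamentals are
energy-normalized shapes and ratios of excitations are unaffected by any
fixed rescaling of a cone's sensitivity.

The cone pairs follow the modern naming convention: normal observers use
$L/M$, protanomalous observers $M'/M$ (a shifted middle-wave variant
paired with the normal M), deuteranomalous observers $L/L'$.

## Constructing observers

Normal fundamentals are built from an A1 visual-pigment absorbance
template evaluated at $\lambda_{\max} = 559, 530, 421$ nm for L, M, S,
screened by lens and macular pigment optical densities,
$\mathrm{cone} = \mathrm{template} \times 10^{-(d_{\mathrm{lens}} + d_{\mathrm{mac}})}$,
and peak-normalized. Pigment optical density and self-screening are
deliberately omitted: sensitivities are treated as normalized shapes, so
only the spectral positions of the pigments carry individual differences.
The template's beta (cis) band is available but off by default — it lies
below 450 nm, where lens screening suppresses it, it cannot influence the
Rayleigh range, and omitting it keeps the bare template strictly unimodal
under frequency translation. A CSV loader (`wavelength_nm,L,M,S`) accepts
tabulated fundamentals when a measured set is preferred.

The shipped pre-receptoral densities are smooth parametric stand-ins for
the standard 2° tables (an exponential lens model, about 1.8 log units at
400 nm, and a Gaussian macular model peaking at 0.35 at 460 nm, negligible
above 550 nm); `readPrereceptoralCsv()` substitutes tabulated templates.
A copy of the parametric model, sampled at 5 nm, ships as
`extdata/prereceptoral_2deg_synthetic.csv` — synthetic by construction,
as the filename says.

Anomalous pigments are constructed by the classical recipe: remove the
pre-receptoral screening from the parent pigment, translate the bare
template rigidly on the frequency (wavenumber) abscissa, and restore the
screening. The translation is implemented as the exact change of variable
$\lambda' = 1/(1/\lambda - s \cdot 10^{-7})$ with linear interpolation,
so the peak lands at $1/(1/\lambda_{\mathrm{peak}} + s \cdot 10^{-7})$:
**positive shifts move the pigment toward shorter wavelengths**. The
strip→restore round trip is the identity to $10^{-9}$ per sample.

`fitShiftToMatch()` inverts the pipeline: it grid-searches shifts (default
step 10 cm⁻¹, bounds ±2000 cm⁻¹, ties toward the smaller $|s|$) for the
one whose predicted match is closest to a target setting — the same
small-step adjustment by which classical anomalous fundamentals were fit
to average empirical matches.

### The zero-shift degenerate case

A protanomalous observer constructed with shift 0 has two *identical*
cones ($M' = M$): its excitation ratio is exactly 1 for every field, every
mixture setting satisfies the match equation, and no unique
$\lambda^\ast$ exists. The solver detects this (all log-ratio differences
identically zero on its scan) and raises a classed `degenerateMatch`
error rather than returning an arbitrary setting. This is the correct
physical reading — an observer whose two Rayleigh-range pigments coincide
is dichromat-like and accepts the whole scale. The *limit* of
$\lambda^\ast(s)$ as $s \to 0$ is well defined (it is the match of the
derivative observer, about 0.97 for the protan branch and 0.83 for the
deutan branch on the Penn-like preset) but differs from the normal
observer's L/M match (0.936): the anomaly branches do not pass through
the normal match at small shifts.

## Instruments

Presets model three devices on a shared grid:

* **penn** — red 623 nm / green 523 nm Gaussians (FWHM 20 / 30 nm),
  amber 592 nm (FWHM 16 nm) screened by a logistic deep-yellow filter
  calibrated analytically so T(590) = 0.90 exactly. The mixture control
  $\lambda \in [0, 1]$ drives the red output as $r(\lambda) = \lambda$
  and the green as constant 1 up to the knee at $\lambda = 0.3$, then
  linearly to 0 at $\lambda = 1$ — the simplest shape consistent with a
  constant-then-falling green and a pure-red endpoint; knee and endpoint
  are config fields. Total mixture output is therefore not constant in
  $\lambda$.
* **oculus** — green 545 / red 670 / amber 589 nm on a 0–73 scale with
  complementary linear outputs (0 = pure green). The green/red peaks are
  typical values for this class of instrument and config-overridable.
* **nagel** — 537 / 666 / 589 nm, narrow (10 nm FWHM), same 0–73
  convention.

LED bandwidths are nowhere tabulated for these devices; the defaults are
plausible for the named LED technologies and are explicit configuration
fields, as is everything else (JSON or list configs override any preset
field). A second Gaussian component is available for the green primary's
long-wavelength shoulder but defaults to amplitude 0 so that unstated
structure never silently biases results. The amber intensity control is
continuous on [0, 2] in relative units.

Because primary radiant outputs are modeled (peak-normalized SPDs with
the linear output curves above), the *positions* of matches on the
control scale are model outputs, not calibrated reproductions of any
physical device's scale. Rescaling both mixture channels by a common
factor provably leaves every predicted match unchanged; rescaling them
differently relabels the control axis by the same monotone map for every
observer, so orderings and agreements between observers are unaffected.

## Numerical choices

Ratios are compared on the log scale for symmetry across observer types.
The solver scans 64 settings, brackets a sign change of
$f(\lambda) = \log r_{\mathrm{mix}}(\lambda) - \log r_{\mathrm{amber}}$,
and bisects to $|f| \le 10^{-8}$ (or a bracket below $10^{-13}$). With
several sign changes — possible with exotic configurations — the crossing
nearest the range midpoint is solved and a note attached; monotonicity of
$f$ over the bracket is checked on the scan and noted if violated. A
brute-force oracle evaluates the mixture SPD explicitly on a uniform
setting grid (ties to the smallest setting) and agrees with the solver to
the oracle's resolution across randomized observers.

The matching range is the connected sublevel set
$|f| \le \delta$ around $\lambda^\ast$, walked outward at $10^{-4}$ of
the control range; $\delta$ (default 0.01 log units) is a free
Weber-like acceptance parameter, as no discrimination threshold is part
of the model. An observer whose range reaches a scale end (`touchesEnd`)
is the "extreme anomalous" case; in this model that arises when the two
pigments nearly coincide (near-dichromacy, e.g. deutan shifts below
about 10 cm⁻¹ at $\delta = 0.01$), while matches themselves stay on-scale
for all template shifts up to the ±3000 cm⁻¹ bound on the shipped
presets — the amber ratio always lies inside the mixture gamut. A
`noMatchInRange` condition (carrying the sign of $f$ at both ends, hence
which end the match lies beyond) arises for off-gamut reference fields,
and simulated studies record such observers as exclusions.

## The synthetic cohort generator

`cohortSpec()` fixes the study conditions; every draw is a pure function
of the spec and its seed, with per-(observer, instrument, session) RNG
streams derived by stable string hashing so any sub-table regenerates
identically.

* **Cohort structure**: 24 normals + 4 protanomalous + 4 deuteranomalous
  by default, the composition of a small laboratory validation cohort
  (32 participants, a quarter anomalous).
* **Anomalous classes**: shifts drawn from
  $\mathcal{N}(-220, 60^2)$ cm⁻¹ (protan, M′ near 536 nm) and
  $\mathcal{N}(+240, 60^2)$ cm⁻¹ (deutan, L′ near 552 nm) — the classical
  anomalous pigment positions. Substantially larger shifts would be
  unphysical in this construction: they carry the variant pigment onto
  the opposite normal pigment, and the predicted match re-converges to
  the normal value.
* **Normal individual differences**: a small jitter shift on the L
  pigment, SD 60 cm⁻¹ (≈ 2 nm of $\lambda_{\max}$ spread, the scale of
  the known L-pigment polymorphism). Differences are spectral, not
  additive offsets on any one instrument's scale, so cross-instrument
  correlations emerge mechanistically from observer metamerism.
  `jitterSdForLambdaSd()` converts a target between-observer SD on a
  given instrument's scale into the jitter SD that induces it, via the
  locally linear shift→match map.
* **Setting noise**: Gaussian on the control scale, homoscedastic, SD
  0.005 per unit of control range (rescaled by each instrument's range
  width), a placeholder for unreported within-observer setting spread;
  settings are clipped to the scale with an explicit flag, never
  silently. Recorded amber intensities are the brightness-equating
  values at the set mixture plus 5% proportional noise.
* **Session plan**: instrument 1 in two sessions (test-retest),
  further instruments in one session, mirroring a two-visit protocol.

What passing simulations do *not* show about real data: the generator has
no learning, fatigue or session-order effects, no adaptation or spatial
field-geometry influences, no optical-density variation, and its noise
model is an assumption — so simulated correlations validate the analysis
machinery and the model's internal consistency, not any particular
device's empirical reliability numbers.

## The analysis layer

Session means are the analysis unit. `correlationTest()` implements the
product-moment coefficient (Spearman = Pearson on midranks) with
two-sided t-approximate p-values on $n - 2$ df, cross-checked in the
tests against `stats::cor.test()`; an exact permutation p is available
for $n \le 8$ as a small-sample cross-check (full enumeration beyond 8
is disproportionate to its diagnostic value). Classification derives
everything from the model itself: the normal range is centered on the
textbook normal observer's predicted match with halfwidth 4× the
between-observer SD induced by the cohort's normal jitter on that
instrument's scale, and the side-to-phenotype mapping is computed from
archetype shifted observers (±230 cm⁻¹), never hard-coded. Boundary
values classify as normal (closed interval). Cross-instrument reports
correlate raw-scale session means — anomalous quotients are deliberately
not used, since they presume identical primaries — and count
contradictory diagnoses (opposite anomalous sides on the two
instruments).

For session means of $n$ settings the expected test-retest correlation is
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2 / n)$; simulated studies recover
this closed form within ±0.05 (mean over 200 replicate studies of 30
normals at $\sigma_b = 0.02$, $\sigma_w = 0.005$, $n = 3$ — about one
minute of compute, the problem size used throughout the acceptance
checks). Including the anomalous classes raises between-observer variance
and with it the all-observer test-retest correlation above the
normals-only value in essentially every replicate, and zero-noise cohorts
are classified identically on both modeled instruments.

## Known limitations

* Matches sit near the red end of both preset scales (normal
  $\lambda^\ast \approx 0.936$ on the Penn-like preset) because primary
  radiant outputs are peak-normalized rather than calibrated; only
  calibrated output curves would reproduce a physical device's scale
  positions.
* The anomaly branches are not anchored to empirical average matches;
  `fitShiftToMatch()` exists to calibrate shifts against any target the
  user supplies.
* Lens/macular densities and the pigment template are smooth parametric
  models; tabulated alternatives are supported via CSV but not shipped.
* The discrimination tolerance $\delta$ is a free parameter; matching
  ranges are comparable within a model configuration, not across
  observers with different criteria.
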