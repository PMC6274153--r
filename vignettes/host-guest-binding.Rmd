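---
title: "Models and methods for 1:1 host-guest binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for 1:1 host-guest binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgbind)
```

# The system and the model

A macrocyclic host H (here cucurbit[7]uril, CB[7] — a rigid barrel of seven
glycoluril units with a hydrophobic cavity and two carbonyl-laced portals)
encapsulates a small-molecule guest G to form a non-covalent inclusion
complex HG. Everything in this package rests on the single-equilibrium 1:1
model

$$ H + G \rightleftharpoons HG, \qquad
   K_a = \frac{[HG]}{[H][G]} \quad (\mathrm{M}^{-1}), $$

together with the two mass balances $[H] + [HG] = H_0$ and
$[G] + [HG] = G_0$. Substituting gives the quadratic
$K_a([H_0]-c)([G_0]-c) = c$ for the complex concentration $c$, whose
physical root is

$$ c \;=\; \frac{2 H_0 G_0}{S + \sqrt{S^2 - 4 H_0 G_0}}, \qquad
   S = H_0 + G_0 + \frac{1}{K_a}. $$

We always evaluate this *conjugate* form. The textbook form
$(S - \sqrt{S^2-4H_0G_0})/2$ subtracts two nearly equal numbers whenever
$S^2 \gg 4H_0G_0$ — precisely the weak-binding/dilute regime titrations
live in — and loses most of its significant digits there; the conjugate
form only ever adds positive quantities. The limits $K_a = 0$ ($c = 0$)
and $K_a = \infty$ ($c = \min(H_0, G_0)$) are handled explicitly rather
than through the formula. The unit tests hold this closed form against an
independent bisection solver to $10^{-10}$ relative error across
$K_a \in [10^1, 10^8]$ and concentrations $[10^{-6}, 10^{-2}]$ M.

Activity corrections, ionic-strength effects and simultaneous multi-complex
speciation (e.g. 1:1 plus 2:1) are out of scope throughout.

# Spectroscopic titrations

## Forward model

UV-vis absorbance at a fixed wavelength and fast-exchange ¹H-NMR chemical
shifts are both population-weighted averages of the free and bound guest
signals:

$$ y_i = y_{\mathrm{free}} + (y_{\mathrm{bound}} - y_{\mathrm{free}})
         \frac{c_i}{G_0}. $$

One functional form serves both modes; molar absorptivities (or limiting
shifts) are folded into the two endpoint parameters, so their units are
whatever the instrument reports (AU, ppm). The model is linear in the two
endpoints and nonlinear only in $K_a$. Slow-exchange NMR series — where
free and bound resonances appear separately and a population-weighted
average is meaningless — are flagged on the input object and refused by the
fitter rather than silently mis-fit.

Samples in these titrations are individually prepared at constant guest
concentration, so no in-series dilution correction is applied (unlike ITC,
below).

## Estimation

`fit_titration()` minimises the residual sum of squares over
$(\log_{10} K_a,\, y_{\mathrm{free}},\, y_{\mathrm{bound}})$ with
Levenberg–Marquardt (`minpack.lm::nls.lm`, cost tolerance $10^{-10}$).
Fitting $\log_{10} K_a$ enforces positivity and evens out the conditioning
across the $10^1$–$10^9$ M⁻¹ range. Starting values come from a grid over
$\log_{10} K_a \in \{0, 1, \dots, 9\}$ with the endpoints initialised to
the first and last observables; among equal-cost grid points the lowest
$K_a$ wins (the conservative choice — weak binding is the null worth
refuting). A series with all-equal observables is rejected as
unidentifiable.

Reported ± values are asymptotic standard errors from the numeric Jacobian
at the optimum, mapped to the $K_a$ scale by the delta method
($\mathrm{se}(K_a) = \ln 10 \cdot K_a \cdot \mathrm{se}(\log_{10}K_a)$).
Published binding studies rarely state their uncertainty method; we default
to the asymptotic errors and offer the bootstrap as the explicit
alternative.

## Bootstrap intervals

`profile_ka_uncertainty()` implements a residual bootstrap: resample
residuals with replacement, add them to the fitted curve, refit, take the
2.5–97.5 percentile range of the bootstrap $K_a$ draws. Two small-sample
conventions matter at the 12-point series sizes used here, and both are
deliberate:

* resampled residuals are rescaled by $\sqrt{n/(n-p)}$, since
  least-squares residuals have variance $(n-p)/n\,\sigma^2$ and the raw
  bootstrap would systematically understate the noise;
* the interval uses the Efron order-statistic convention (the
  $\lfloor (B{+}1)\alpha \rfloor$-th smallest draw), not interpolated
  quantiles.

Even so, percentile intervals at $n = 12$ undercover somewhat (measured
~88% at nominal 95% on the designs below); users who need calibrated
small-sample intervals should raise the number of titration points rather
than trust the nominal level. The interval is deterministic for a fixed
seed, and the seeded RNG stream is isolated from the caller's.

# Isothermal titration calorimetry

## Dilution bookkeeping

The calorimeter cell is overfilled: injecting $dV_i$ of titrant displaces
an equal volume of cell contents. We adopt the recursive overflow model

$$ M_i = M_{i-1}\left(1 - \tfrac{dV_i}{V_0}\right), \qquad
   X_i = X_{i-1}\left(1 - \tfrac{dV_i}{V_0}\right)
       + X_{\mathrm{syr}} \tfrac{dV_i}{V_0}, $$

with guest $M_0$ the initial cell concentration and host $X_0 = 0$. Vendor
packages differ in their dilution conventions; this one was chosen because
it conserves moles exactly and is therefore testable against direct
bookkeeping (the suite checks a 10-injection schedule against the
closed-form geometric product, and cumulative heats against a
mole-tracking oracle to $10^{-9}$ relative).

## Heat model and fit

With an effective binding-site concentration $n M_i$ (one fitted site
parameter $n$, as in the standard single-site calorimetry model), the
complex concentration after injection $i$ is
$c_i = c(X_i,\, n M_i,\, K_a)$ from the exact 1:1 solver, and the heat of
injection $i$ is

$$ q_i = \Delta H \, V_0 \left( c_i - c_{i-1}\big(1 - \tfrac{dV_i}{V_0}\big) \right), $$

the second term crediting complex expelled during the injection. Heats are
stored in µcal and $\Delta H$ in kcal/mol; the conversion is
1 kcal = 10⁹ µcal, pinned by a dedicated unit test in the stoichiometric
limit ($K_a \to \infty$, where $q_i = \Delta H \times$ moles injected,
exactly). An optional constant per-injection offset models heats of
dilution (default 0; can be fitted).

`fit_itc()` runs the same Levenberg–Marquardt machinery over
$(n,\, \log_{10} K_a,\, \Delta H)$, initialised at $n = 1$,
$\Delta H = q_1 / \text{moles in injection 1}$ and a grid-searched
$\log_{10} K_a$. $\Delta G = -RT\ln K_a$ and $T\Delta S = \Delta H -
\Delta G$ are filled in as identities — never fitted — so every result
satisfies them to machine precision by construction. When the final molar
ratio never reaches the fitted $n$ the saturation plateau is unobserved
and the result carries an `identifiability_low` flag instead of a silently
confident answer.

The dimensionless $c$-value $K_a M_0 n$ governs curve shape: parameter
recovery under 2% heat noise is verified to stay within 10% median
relative error for $c \in [1, 1000]$; outside that window (notably
$c \lesssim 1$, which includes real weak binders measured at 0.05 mM) the
uncertainty grows quickly and the standard errors reflect it.

Default schedule: 200 µL cell, 20 × 2 µL injections, 2 mM syringe,
298.15 K — a typical small-volume calorimeter protocol; all of it is
configurable, since published studies rarely print their schedules.

# Job (continuous-variation) analysis

At constant total concentration $C_{tot}$, sample $x$ has
$H_0 = x\,C_{tot}$ and $G_0 = (1-x)\,C_{tot}$. For any 1:1 complex the
complex-concentration curve is symmetric in $x \leftrightarrow 1-x$ and
peaks at $x = 0.5$ regardless of $K_a$ or $C_{tot}$; a single
$\mathrm{H}_m\mathrm{G}_n$ complex peaks at $x = m/(m+n)$. That makes the
peak position a stoichiometry diagnostic, and the package includes a
generalised single-complex $m{:}n$ solver (bisection on the extent of
reaction, $m, n \le 3$) purely to demonstrate the discrimination — e.g. a
1:2 host:guest complex peaks at $x = 1/3$.

`job_maximum()` takes the best grid point and refines between its
neighbours by golden-section search on the exact model curve (tolerance
$10^{-8}$ in $x$); for purely empirical curves with no model attached it
falls back on the parabola through the three points around the grid
maximum, which is as much resolution as 11 noisy points support. A flat
curve (e.g. $K_a = 0$) has no maximum and raises an error. The default
grid is 11 evenly spaced mole fractions — a typical continuous-variation
series; the studies this emulates do not print their grids.

# Thermodynamic identities and auditing

Two identities connect every table of binding thermodynamics:

$$ \Delta G = -RT \ln K_a, \qquad T\Delta S = \Delta H - \Delta G, $$

with $R = 1.987204 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ (thermochemical
calorie). `audit_record()`/`audit_thermo_table()` recompute both residuals
for any record that carries enough fields and compare them to a tolerance
(default 0.01 kcal/mol — one unit in the last digit of a 2-dp table). A
check passes only when the absolute residual is *strictly* below the
tolerance (after rounding away float noise at the ninth decimal), so a row
that is off by exactly one printed unit is flagged, not excused. Records
without enough fields produce an explicit "insufficient" report rather
than a vacuous pass.

Two numerical conventions worth making explicit:

* **Temperature.** The default is 298.15 K. The published free energies
  shipped in `published_thermo()` (−6.85, −5.21 kcal/mol from the
  spectroscopic $K_a$ values) reproduce at 2 dp at 298.15 K but not at
  297.5 K, although the source table prints the latter beside its
  formula; the audit surfaces rather than hides such discrepancies.
* **Rounding.** Energies are reported at 2 dp with round-half-even; full
  precision is kept internally.

Running the audit over the shipped table of published values flags exactly
three identities: both identities of the cimetidine calorimetry row
(residuals 0.017 and 0.030 kcal/mol — plausibly unrounded inputs upstream,
undecidable from the printed record) and the famotidine end-point
decomposition column (residual exactly 0.010). Computing the end-point
(MM-GBSA) energies themselves is out of scope; only their printed
decomposition is audited.

# ESI-MS adduct assignment

Monoisotopic masses are sums over an embedded most-abundant-isotope table
(¹²C 12 exactly, ¹H 1.0078250319, ¹⁴N 14.0030740052, ¹⁶O 15.9949146221,
³²S 31.97207069, ³¹P 30.97376151 Da). A protonated adduct
$[a\mathrm{H} + b\mathrm{G} + z\mathrm{H}^+]^{z+}$ has

$$ m/z = \frac{a M_{\mathrm{host}} + b M_{\mathrm{guest}} + z\,m_p}{z}, $$

with the *proton* mass $m_p = 1.00727646688$ Da per charge — not the
hydrogen atom mass; at 2 dp and $z = 2$ the electron mass matters.
Monoisotopic (not average) masses are what reproduce the "calculated"
values quoted with high-resolution spectra: for the three drug@CB[7]
complexes the doubly protonated 1:1 adducts compute to 708.24 (cimetidine),
750.70 (famotidine) and 747.74 (nizatidine) Th. `assign_peak()` enumerates
compositions up to `max_n` of each partner, keeps candidates within a ppm
window (default 30 ppm — a conservative external-calibration figure, a
convention rather than a measured one) and ranks by absolute ppm error
with ties to the smaller adduct. Isotope-pattern simulation and non-proton
adducts (Na⁺/K⁺) are out of scope.

The molecular formulas shipped in `hg_formulas()` (CB[7] C42H42N28O14,
cimetidine C10H16N6S, famotidine C8H15N7O2S3, nizatidine C12H21N5O2S2) are
standard chemical identities of these compounds, included as a reference
table.

# Synthetic data: what it emulates and what it does not

The generators produce datasets with the statistical structure the fitters
assume: exact forward-model curves plus additive homoscedastic Gaussian
noise, seeded so identical configurations are bit-identical.
`study_design()` encodes the six designs used to characterise the three
H₂-antagonist drugs — famotidine UV-vis (0.05 mM guest, 0–6 equivalents),
nizatidine UV-vis (0.04 mM, 0–3 equivalents), cimetidine ¹H-NMR (1.0 mM,
0–3 equivalents), and ITC runs titrating 2 mM CB[7] into 0.05–0.1 mM drug
— with the published fitted parameters as generating truths. Where a
design detail is unpublished, a stated convention stands in: 12 evenly
spaced titration points, 11-point Job grids, the 20 × 2 µL ITC schedule,
spectroscopic signal endpoints of plausible sign and size, and noise
levels expressed as a fraction of dynamic range (1% spectroscopic, 2%
calorimetric are the realistic reference choices).

What passing round-trip tests on such data shows: the estimation chain is
self-consistent — it recovers, to 0.1% (spectroscopic) and 0.5% (ITC, all
three parameters), the parameters that generated noiseless data, and
degrades gracefully under realistic noise. What it does not show: anything
about instrument systematics absent from the noise model — baseline drift,
heteroscedastic photometric error, NMR phase/baseline artefacts, ITC
first-injection anomalies (an optional discard flag exists, default off),
or chemistry outside the single-equilibrium model. Claims about real data
rest on the model being right, not on these tests.

Problem sizes throughout the test suite (grids of ~100 equilibrium points,
200-replicate noise sweeps, 200-draw bootstraps over 20 seeds) were chosen
as the smallest that exercise each property convincingly.

# The pipeline

`run_pipeline()` ties the stages together from one JSON config — generate
or read datasets, fit each, audit a parameter table, and write
`summary.csv` / `audit.csv` / `report.json` with provenance (seed, package
version, config hash; the timestamp is confined to the provenance block so
reruns are otherwise byte-identical). Concentrations in user-facing files
carry unit suffixes (`_mM`, `_uL`, `_C`) and are converted to SI at parse
time, so a bare number can never silently change meaning. Full precision
goes to the CSVs; rounding happens only in printed summaries.

# Known limitations

* Single equilibrium only; no global multi-wavelength or multi-technique
  fits.
* The ITC model consumes integrated per-injection heats; raw power traces
  and baseline integration are upstream of this package.
* Percentile bootstrap intervals undercover at small $n$ (above).
* The $m{:}n$ solver exists for stoichiometry discrimination, not for
  fitting $m{:}n$ titration data.
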