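---
title: "Modelling biosulfidogenesis in acidic pit-lake microcosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biosulfidogenesis in acidic pit-lake microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfidogen)
```

## The system being modelled

Acidic pit lakes (APLs) are flooded abandoned open-cast mines: low pH, very
high sulfate, and dissolved metal(loid)s. In a permanently stratified
(meromictic) APL the deep layer never mixes with the surface, so metals
precipitated there as sulfide minerals stay sequestered in the bottom
sediments. Dissimilatory sulfate reduction — microbial respiration of
SO₄²⁻ to S(-II) by acid-tolerant sulfate-reducing bacteria (SRB) — supplies
that sulfide and generates alkalinity, but the deep layer is typically
carbon-limited. `sulfidogen` implements the quantitative analysis of
microcosm experiments in which high-density biomass (dried microalgae,
pelletized duckweed) and individual biocomponents (amino acids, sugars,
long-chain fatty acids) are dosed into deep-layer water as electron donors,
plus the whole-lake dosing arithmetic that scales the bench results to a
remediation scenario.

## Sulfide production kinetics

Replicate bottles are sampled over days to weeks; sulfide (µM) rises after
a lag, approximately linearly, then plateaus when the labile substrate
fraction is exhausted. The kinetic description is deliberately zero-order:

* **Window rule.** Finite-difference rates between consecutive samples are
  compared against a threshold (default 50 µM/d, i.e. 0.05 mM/d). The
  production window opens at the left endpoint of the first interval whose
  rate exceeds the threshold and closes at the left endpoint of the first
  subsequent interval whose rate falls below it (or at the last sample).
* **Lag** is the window start, reported at sampling-time resolution; no
  interpolation is attempted between samples.
* **Rate** is the endpoint slope over the window:
  `(S(end) − S(start)) / (end − start)`.
* **Maximum sulfide** is the maximum observed value, not a fitted plateau.
* **Per-dose normalisations**: efficiency = max sulfide / COD dose
  (µM per mg L⁻¹ O₂) and yield = max sulfide / mass dose (mM per g).

Treatment statistics (mean, sample n−1 sd) are computed over *producing*
replicates only; `n` in a treatment summary counts replicates whose series
yielded a window, so a substrate where one bottle in four produced reports
`n = 1` with no sd.

The threshold is configurable for a documented reason: several reported
treatments produce sulfide at rates at or below 50 µM/d (lipids at
3–9 µM/d, one microalga at 33 µM/d). Under the literal rule those
treatments have no window; analyses of slow treatments must lower the
threshold and say so. Negative interval rates are reported in diagnostics
but never open a window.

## Reaction thermodynamics

Substrate oxidation coupled to sulfate reduction is balanced from
degree-of-reduction bookkeeping. For a C/H/O/N substrate, the electrons
released on complete oxidation to CO₂, NH₄⁺ and H₂O are
`e = 4C + H − 2O − 3N − charge`; sulfate accepts 8 electrons per sulfide
formed, so the reaction is

```
substrate + (e/8) SO4^2- + h H+  ->  C CO2 + (e/8) H2S + N NH4+ + w H2O
```

with `h` and `w` closing the hydrogen and charge balances. All
coefficients are multiples of 1/8 and exactly representable in binary, so
`is_balanced()` verifies conservation on 8×-scaled integer coefficients —
an exact check, not a tolerance comparison.

Energies are evaluated per mole of substrate carbon:
`ΔGr′ = ΔGr° + R·T·lnQ / (1000·nC)`, with `ln Q = Σ νᵢ ln aᵢ`. Numerical
choices, all deliberate:

* Activities equal concentrations (partial pressure for gaseous CO₂,
  water activity 1); no activity-coefficient model. The shipped lake
  conditions are T = 291 K, pH 4.2, {CO₂} = 0.05 atm, {SO₄²⁻} = 0.14 M,
  {NH₄⁺} = 0.01 M, {H₂S(aq)} = 10⁻⁶ M, and the initial substrate
  molarities.
* ΔGr°(298 K) is used with RT(291 K)·lnQ; no van 't Hoff correction over
  the 7 K gap. The residual this leaves is below ~3 kJ/mol C, which is the
  tolerance the package claims for recomputed condition-adjusted energies.
* The reaction fixture stores the published table verbatim, including two
  known label/formula swaps (the alanine/glycine and palmitate/oleate
  rows) and one row (R2) whose printed coefficients are not element- or
  charge-balanced — `balance_sulfate_coupling()` follows conservation and
  yields one NH₄⁺ per substrate nitrogen instead. Condition-adjusted
  energies are recomputed from the *printed* stoichiometries and printed
  ΔGr° values so that the comparison isolates the reaction-quotient term;
  with the corrected R2 stoichiometry the recomputed value moves ~5 kJ/mol C
  away from the printed one, consistent with the published number having
  been evaluated on the printed coefficients.
* The formation-energy fixture is provenance-tagged. Standard-compilation
  values reproduce the glucose ΔGr° (≈ −121 kJ/mol C); the long-chain
  fatty-acid anions carry group-additivity estimates and are excluded from
  any assertion. Published ΔGr° values are always used as the starting
  point for condition-adjusted energies.

The theoretical ceiling on sulfide per unit chemical oxygen demand follows
from electron bookkeeping alone: 1 mg O₂ ≡ 1/32 mmol × 4 e⁻, and 8 e⁻ per
S(-II), giving 15.625 µM sulfide per mg L⁻¹ COD (`max_sulfide_per_cod()`).
Measured efficiencies of 0.5–2.7 µM per mg L⁻¹ show how far from complete
the biological utilisation is.

## Volatile fatty acids and pH

Fermentation intermediates (acetate, butyrate) accumulate during substrate
oxidation and buffer the solution against the alkalinity that sulfate
reduction generates. The module implements the Henderson–Hasselbalch
relation, the monoprotic buffer-capacity formula

```
beta = 2.303 ( Kw/[H+] + [H+] + C·Ka·[H+] / ([H+] + Ka)^2 )
```

and a charge-balance pH solver for weak-acid mixtures (superposition of
monoprotic terms — an extension beyond the single-acid formula, stated as
such). The solver brackets log₁₀[H⁺] on [−14, 1] and polishes to a
residual below 10⁻¹² eq/L.

One regime caveat worth stating precisely: at half-neutralisation
(base = C/2) the exact charge-balance pH approaches pKa only as the
free-proton correction [H⁺]/C becomes small. With acetate (pKa 4.76,
[H⁺] ≈ 1.7×10⁻⁵ M near pKa) agreement to < 0.01 pH units requires
C ≳ 5 mM; at C = 10⁻⁴ M the deviation is ~0.16 units. That is the
textbook limitation of the approximation, not solver error. The package
does not attempt to reproduce the "0.5-unit lower pH" comparison between
acetate- and butyrate-dominated bottles as a numeric target, because the
construction (what is held equal between the two solutions) is
under-determined; the tools to explore it are exported instead. Ionic
strength and temperature corrections to Kw and pKa are omitted — textbook
constants throughout. Carbonate-system chemistry and Fe/Al hydrolysis
acidity are out of scope.

## Whole-lake dosing

The engineering chain is transparent arithmetic, kept as separate exported
steps so each number in a plan traces to one operation: stoichiometric
sulfide demand (ZnS 1:1, As₂S₃ 3:2, FeS 1:1 — FeS excluded from the
default inventory since iron is deliberately left in solution to preserve
density stratification); a safety-factored target (the reference scenario
uses an absolute 3 mM); dose = target / yield ratio; mass = dose × volume;
and volumetric normalisations. Conventions: US short ton = 907.185 kg,
1 Mgallon = 3.785 ML, 365-day years for flow volumes. The published
volumetric figure of ~2.81 t/ML derives from the *rounded* 350-US-ton
mass; the unrounded chain gives 2.83 t/ML, and both paths are exercised in
tests. The companion "US tons per Mgallon" figure printed alongside
(10.6) is not consistent with its own metric value under these
conversions (2.81 t/ML × 3.785/0.907185 = 11.7); the package implements
the unit-faithful conversion, which does reproduce the passive-treatment
comparison figure (0.48 t/ML → 2.01 US tons/Mgal). Layer densities are
carried on a plan as advisory context only — no stratification mechanics
are modelled.

## Small-sample inference

With n ≤ 4 replicates per treatment, asymptotic tests are inappropriate,
so the Mann–Whitney U test is exact by construction: U from midrank sums,
and the p-value as the fraction of all `choose(n1+n2, n1)` group labelings
of the pooled data with a statistic as or more extreme — valid under
exchangeability, ties included. Enumeration applies up to n₁+n₂ = 12;
beyond that a tie-corrected normal approximation with continuity
correction takes over. "Paired" comparison of treatments is read as
*pairwise* application of the two-sample test over all treatment pairs
(replicates are not matched across treatments); tests are two-sided by
default, and no multiple-testing correction is applied by default (a Holm
option exists). Kendall's τ-b handles ties in both margins, with exact
permutation p-values up to n = 8. Independent oracles in the test suite —
pair-counting enumeration, `wilcox.test`, `cor.test` — validate both
routes.

## The synthetic-data generator

There are no public per-bottle measurements, so the generator is the
package's test bed. Its design mirrors the fitting model deliberately:
replicate parameters (lag L, rate k, plateau Smax) are drawn from
truncated-at-zero Gaussians around treatment means; sulfide follows the
piecewise-linear `clamp(k(t − L), 0, Smax)`; additive Gaussian noise
(default sd 10 µM, the order of colorimetric-assay scatter implied by
replicate spreads) is clipped at zero. Because generator and fit share
the functional form, noiseless aligned sampling is recovered *exactly* —
a sharp regression test. Co-trajectories derive from the noiseless curve:
metals deplete stoichiometrically in the order As → Zn → Fe (faster
arsenic-sulfide precipitation; configurable); pH interpolates from 4.2
toward a treatment-specific ceiling with the cumulative sulfide fraction;
acetate rises from the lag to a mid-production peak then decays, butyrate
onsets at the plateau and persists.

Calibrated presets encode the nine published treatments. Where the source
reports ranges rather than means (monosaccharide and lipid lags and
rates), the presets assign endpoints consistent with the reported
ordering; maxima for those treatments derive from the per-COD efficiencies
times the measured COD doses; two biomass mass doses are back-computed
from per-gram yields and flagged `back_computed` in the substrate fixture.
The oleate preset uses a producing fraction of 0.25 (one bottle in four).

**Sampling schedules** are not reported and are a design choice with real
consequences. Finite-difference rates have noise sd `√2·σ/Δt`; half-day
intervals at σ = 10 µM give ±28 µM/d slope noise, which overwhelms
threshold crossings, while multi-day intervals cannot resolve a 4.3-day
lag. The presets therefore sample at half-day resolution only in a short
expected-onset window and at 1–3 day steps elsewhere — standard bench
practice, and the compromise that keeps both failure modes small. For the
same reason, *parameter-recovery* analyses detect the window at 60% of
the expected treatment rate: the 50 µM/d rule threshold lies within slope
noise of the fastest treatment's rate (59.6 µM/d), so first-crossing
detection at the rule threshold is systematically biased for exactly the
treatments the rule was written for. Rule-faithful analyses of measured
data keep the 50 µM/d default.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real microcosms: substrate depletion feedback and
non-constant rates within the window, sulfide reoxidation, assay
calibration drift, correlated errors within a bottle, inoculum
(filter-wedge) effects between replicates, and any community dynamics.
Problem sizes in the test suite (100 replicates for recovery studies,
1000 random formulas for conservation properties, complete enumeration up
to group sizes of five) were chosen to exercise the estimators'
distributional behaviour at desk scale.

## The pipeline

`run_pipeline()` chains simulate/ingest → kinetics → pairwise statistics →
recomputed reaction energies → dosing plan, writing six artifacts plus a
manifest with the seed, thresholds and artifact checksums. The pipeline is
a pure function of (input, config, seed): identical configuration gives
byte-identical bundles, which the test suite asserts. All randomness flows
from the seed; no stage keeps hidden state.

## Known limitations

* Zero-order kinetics only; no Monod/Gompertz fitting (out of scope by
  design — the source analysis chose zero-order fits).
* Lag is quantised to the sampling grid; with noisy data near the
  threshold, first-crossing detection is biased unless the threshold sits
  well below the expected rate (see above).
* Thermodynamics stops at fixed activities: no speciation, no ionic
  strength, no H₂S/HS⁻ equilibrium beyond treating {H₂S(aq)} as given.
* The dosing module is static stoichiometry — no kinetic coupling between
  dose, in-lake rates and stratification stability.
* 16S amplicon community analysis is entirely out of scope; published
  pipelines (DADA2, phyloseq) cover it.
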