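---
title: "Trait variation, trait spectra and driver attribution: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait variation, trait spectra and driver attribution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspectra)
```

# The scientific problem

Widespread plants — invasive species especially — occupy habitats that
differ in climate, soil, neighbours and the plant's own impact on its
community. Two population-level responses summarise how they cope: how
much each functional trait varies across populations, and how traits
covary (the trait *spectrum*, here the relationship between leaf
production potential and leaf stress-tolerance potential). This package
implements a complete analysis chain for surveys with a paired
invaded/uninvaded plot design: per-unit trait indices, a comparison of
variation across traits, model II fits of the spectrum, and an
exhaustive model-averaging attribution of both to 16 drivers in four
categories (climate, native plant diversity, soil properties, and
invader–community interactions).

# Indices

For a trait $T$ over units $i$:

* **PVI** $= \dfrac{\max(T) - T_i}{\max(T) - \min(T)} \in [0, 1]$. Note
  the orientation: the unit at the sample **maximum scores 0** and the
  minimum scores 1. We implement the index exactly as defined in the
  survey literature it comes from and do not reorient it. The extremes
  are taken from a `reference` table that defaults to the scored table
  itself; passing population-level aggregates as the reference lets you
  score plot-level units against population-level extremes (the two unit
  scopes such surveys mix). PVI requires a non-degenerate range and is
  invariant under positive affine transforms of the trait.
* **LPI** $= \sum_{j=1}^{4} T_{ij}/\max_i(T_{ij})$ over leaf area, SLA,
  chlorophyll and leaf N; **LTI** analogously over LDMC, leaf C and leaf
  C:N. Each term is max-normalised, so both indices are invariant to
  rescaling any single trait column; the upper bounds 4 and 3 are
  attained only by a unit that is maximal in every constituent trait.
* **Spectrum ratio** $= \mathrm{LTI}/\mathrm{LPI}$, the per-unit scalar
  position on the production–tolerance spectrum.
* **Relative change** $\Delta = (V_i - V_u)/(V_i + V_u) \in [-1, 1]$ for
  a variable measured in an invaded plot and its paired uninvaded plot;
  antisymmetric in its arguments, undefined when both values are zero.

SLA is leaf area over dry mass (cm² g⁻¹); LDMC is dry over
water-saturated fresh mass, reported in mg g⁻¹ (the ratio × 1000, the
unit convention of the trait handbooks). Leaf C:N is recomputed from
leaf C and leaf N when absent; if supplied and inconsistent beyond 1e-6
relative, the supplied column wins with a warning — an explicit
tie-break in favour of the measured value.

# Model II regression

Trait–trait and LPI–LTI relationships are standardized major axis fits:
$|b| = s_y/s_x$ signed by the correlation, intercept through the
bivariate mean, and the test of $r = 0$ (t, $n-2$ df) as the
significance test — the conventional choice for SMA. Trait–trait fits
are computed on natural-log scale by default (traits are positive and
right-skewed); the LPI–LTI fit is on the raw index scale because the
indices are already normalised composites. No multiple-testing
correction is applied across the 21 trait pairs by default, matching
standard practice for these descriptive fits.

# ANOVA and compact letters

Per-trait PVI distributions are compared by one-way ANOVA with Tukey HSD
at $\alpha = 0.05$ (the standard all-pairs post-hoc). The letter display
is computed as an exact minimum clique edge cover of the
"not significantly different" graph (exhaustive over maximal cliques for
up to 12 groups, greedy beyond): groups share a letter iff their
difference is not significant, with the smallest possible number of
letters. Letters are assigned in order of decreasing group mean.

# Multimodel inference

For response $y$ and $p$ drivers (the survey set has $p = 16$):

1. predictors are z-scored so averaged coefficients are comparable
   across drivers (effects are reported on the standardized scale);
2. all $2^p$ OLS models (always including an intercept) are fitted.
   Implementation detail: the Gram matrix of the full design is computed
   once and each subset costs one small Cholesky solve, in compiled
   code; $2^{16}$ models at $n = 300$ take on the order of a second;
3. models are ranked by the small-sample criterion
   $\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1}$
   with $k$ = subset size + 2 (intercept and residual variance both
   counted — the least-squares convention). Ties are broken by the
   subset bitmask so output is deterministic; subsets violating
   $n - k - 1 > 0$ are skipped with a warning;
4. Akaike weights $w_m \propto e^{-\Delta_m/2}$; the **confidence set**
   is the smallest AICc-ordered prefix with cumulative weight ≥ 0.95
   (crossing model included);
5. coefficients are averaged over the confidence set with
   **zero substitution** (a model not containing a driver contributes a
   zero coefficient), weights renormalised within the set; the
   unconditional SE is $\sqrt{\sum_m w_m\,(se_m^2 + (b_m - \bar b)^2)}$,
   with a two-sided normal test. Full averaging is the default because
   importance and effect direction are interpreted jointly across the
   whole set; conditional averaging is available via a flag;
6. **importance** of a driver is the summed weight of all candidate
   models containing it (over the full set); **relative contribution**
   is importance divided by total importance (%, summing to 100);
   category totals are sums over members and per-capita contributions
   divide by member count; a configurable biotic flag (default: the 11
   biotic drivers are richness, evenness, bacteria, fungi, F/B and the
   six Δ variables) yields the biotic/abiotic split.

Two analysis choices are deliberately exposed rather than fixed, because
the survey designs this package targets leave them ambiguous: the unit
scope (300 plot pairs or 66 site-level populations; `scope` in
`run_pipeline()`) and the response definition for "variation in a trait"
(we use the per-unit PVI of that trait, and the LTI/LPI ratio for the
spectrum; any column can be passed to `mmi()` directly). Soil texture
enters as a single continuous variable (sand fraction by default)
because a clay/silt/sand composition does not define a scalar.

# The synthetic survey generator

The generator emulates the survey geometry end to end: 22 locations × 3
sites, five plot pairs at the first 51 sites and three at the remaining
15 (300 pairs, 66 populations), with one analysis unit per pair and an
option to aggregate to populations.

* Nine **base drivers** (MAT, MAP, richness, evenness, pH, texture,
  nutrients, bacteria, fungi) are drawn site-level from a multivariate
  Gaussian with configurable means, SDs and a 9 × 9 correlation
  (identity by default), then clamped to admissible ranges (nonnegative
  pools, evenness in [0,1], texture in [0,100]). Climate is held
  constant within a location. Defaults describe a subtropical lowland
  survey region: MAT 16 ± 2 °C, MAP 1400 ± 300 mm, richness 12 ± 4
  species, evenness 0.65 ± 0.12, pH 6.5 ± 0.7, sand 40 ± 12%, available
  nutrients 60 ± 18 mg kg⁻¹, bacterial and fungal PLFA 50 ± 12 and
  12 ± 2.5 nmol g⁻¹. The microbial CVs are kept near 0.2–0.25 so pools
  stay biologically plausible (soils are never microbe-free); letting
  them approach zero makes paired relative changes saturate at ±1 and
  produces artefactual heavy tails.
* The five **paired variables** (richness, pH, nutrients, bacteria,
  fungi) get uninvaded-plot values (site value + pair noise) and
  invaded-plot values (uninvaded + invasion shift + pair noise);
  defaults encode a typical invasion footprint (richness −3 species,
  pH −0.2, nutrients +8, bacteria +5, fungi +2). F/B is
  fungi/bacteria, and the six Δ drivers are the paired relative changes;
  all seven are **derived, not drawn**, which is why the correlation
  parameter covers only the nine base drivers. If clamping zeroes a
  variable in both plots of a pair, its Δ is set to 0 (no change).
* **Traits** are `baseline + Z·b + ε` with `Z` the z-scored 16-driver
  matrix, `b` a 16 × 7 effect matrix (trait units per driver SD) and
  Gaussian residuals; draws that would go nonpositive are resampled (at
  most 100 times, then an error). Leaf C:N is derived as leaf C / leaf N
  by default so the trait table is internally consistent; a `direct`
  mode generates it from its own effect column instead. The default
  effect matrix encodes a production/tolerance trade-off (resource
  drivers raise production traits and depress tolerance traits;
  temperature does the opposite), so simulated surveys show a negative
  LPI–LTI relationship of realistic strength (r² ≈ 0.55–0.6) — a
  structural choice, not a fit to any published value.
* One integer seed feeds separate streams for the environment and trait
  stages, so `generate_traits()` is reproducible given an environment
  table regardless of how that table was produced.

What the generator does **not** emulate: spatial autocorrelation beyond
the location/site hierarchy, non-Gaussian driver distributions,
measurement error models for the lab assays, and community composition
beyond scalar microbial pools. Tests passing on synthetic surveys
therefore validate the statistical machinery and its contracts, not
field-data idiosyncrasies such as outliers, missingness or confounded
gradients.

# The recovery study and an identifiability caveat

`recovery_experiment()` plants known effects on four drivers
(standardized slopes 0.5–1, random signs, residual SD 1, n = 300) and
checks that they occupy the top-4 importance ranks with correctly signed
averaged coefficients. The four true drivers are sampled from the twelve
*identifiable* drivers: `fb_ratio`, `d_bacteria`, `d_fungi` and
`d_fb_ratio` are excluded as candidates (while remaining in every
candidate model as confounders). The reason is structural, not a
convenience: to first order the relative change of F/B equals
Δfungi − Δbacteria, and F/B itself is linear in fungi and bacteria near
their means, so these drivers lie in each other's span. An effect
planted inside that span has no unique generating driver — the same
response is obtained from different "true" quartets — and asking any
selection method to rank one specific member on top is ill-posed. Real
surveys that carry a ratio and its components as separate drivers have
exactly the same degeneracy; grouped (category-level) contributions
remain meaningful there, which is one reason the per-category
decomposition is the headline output.

# Numerical choices and degenerate inputs

* AICc ties broken by subset bitmask; rank-deficient subsets (Cholesky
  failure) and perfect fits (RSS = 0, degenerate likelihood) are dropped
  with warnings rather than aborting the enumeration.
* Zero-variance responses or predictors, constant trait vectors
  (PVI), zero-variance SMA axes, `vi + vu = 0` in Δ, and undersized
  ANOVA groups all raise typed errors (`leafspectra_*_error`) naming the
  offence.
* Interchange CSVs are written at 12 significant digits, which makes
  reruns byte-identical while keeping round-trip error below 1e-9
  relative.
* Oracle comparisons in the test suite run the whole averaging chain
  against an independent `lm()`-refit implementation at p ≤ 4, n ≤ 60
  (tolerance 1e-8); the recovery study uses 100 replicates of the full
  2^16 enumeration at n = 300. These sizes were chosen so the entire
  suite exercises every code path at full survey scale while remaining
  quick to run on a laptop.

# Known limitations

* Exhaustive enumeration is exponential in p; the compiled kernel is
  comfortable to p = 16–20 but this package deliberately offers no
  stepwise or genetic shortcut (out of scope by design).
* No mixed-effects or spatial error structures in the candidate models;
  the paired/nested survey structure enters only through the generator
  and the unit-scope choice.
* SMA fits come without bootstrap confidence intervals; the p-value is
  the correlation test.
* The replication helper `replicate_benchmarks()` expects a raw
  per-population trait table; the original survey's deposited table is
  not redistributed with the package, so the published-value replication
  runs only when a user supplies that file.
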