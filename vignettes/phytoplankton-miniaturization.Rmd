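---
title: "Detecting and attributing phytoplankton miniaturization at species and community scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and attributing phytoplankton miniaturization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytosize)
```

## The problem

Cell size is a master trait of phytoplankton: it sets nutrient uptake,
sinking speed, grazing exposure and carbon export. Decadal monitoring
records — monthly counts and mean cell biovolumes per species at a network
of coastal stations — make it possible to ask whether phytoplankton are
getting smaller, and crucially *how*: a community's mean cell size

$$C = \frac{\sum_i n_i v_i}{\sum_i n_i}$$

can fall because individual species shrink (a within-species *size shift*,
the temperature–size rule's prediction under warming) or because the
community drifts toward a larger share of small-bodied species (a
*species shift*, the community-scale reading of Bergmann's rule). The two
mechanisms have different causes and different ecological consequences, and
they can offset: widespread species-level shrinkage can coexist with a
stable or even growing community mean size if the abundance share of small
species falls at the same time. `phytosize` implements the full analysis
chain that separates these signals and attributes them to environmental
drivers.

## Measurement model and conventions

* **Time axis.** Dates carry year and month only; the regression axis is
  the *lagged month*, the whole number of months since the first sample
  (origin = 0). Sampling is monthly, so finer granularity carries no
  information.
* **Size.** Body size is cell biovolume in μm³. Size responses are modelled
  on the log scale throughout: biovolumes span about five orders of
  magnitude across species, and the temperature–size literature reports
  proportional effects (≈2.5 % volume loss per °C in protists), so additive
  models on the raw scale would be dominated by the largest taxa. Where a
  species is absent from a sample its biovolume is *missing*, never zero —
  a zero biovolume is biologically meaningless.
* **Species series.** At station scope the species' series is the sample
  value; at zone or region scope it is the unweighted mean over the
  stations reporting the species that month. Unweighted, because an
  abundance-weighted mean would let a single bloom station dominate the
  regional size signal; an abundance-weighted variant can be had by
  aggregating manually.
* **Small species.** The small set is the bottom quartile (`q = 0.25`,
  floor rounding, at least one species, ties broken by species id) of all
  species ranked by their average biovolume pooled over all communities.
  Small% is the *abundance share* of these species by default — declines in
  field data trace to reduced relative abundance of small taxa — with a
  richness-share variant behind `weighting = "richness"`. The ranking pools
  the full record rather than being recomputed per window, so membership of
  the small set is a fixed attribute of a species within one analysis.
* **Detection limits.** Environmental values reported as `"<limit"` are
  replaced by half the limit by default (the common monitoring convention;
  `zero` and `asis` rules are available) and flagged. The N/P ratio is
  computed on a molar basis so it is comparable to the Redfield value of
  16; whether a phosphate column is μg P/L or μg PO₄/L is a reader switch
  (`po4_as_p`), defaulting to μg P/L.

## Trend estimation

`linear_trend()` fits OLS against lagged month and reports the slope per
month and per year, the two-sided t-test on the slope (n − 2 df), and r².
Conventions for degenerate input: a constant series has slope 0 and p = 1
(so screening loops never propagate NaN); a non-constant series fitted
exactly is flagged `exact_fit` with p = 0. Missing months are simply
omitted from the fit.

`stl_decompose()` performs the LOESS-based seasonal–trend decomposition
with period 12 (an annual cycle in monthly data). The seasonal window is
"periodic" by default — the seasonal pattern is assumed stable across
years — and the trend window is STL's standard
`nextodd(ceiling(1.5·period/(1 − 1.5/s.window)))`. Internal gaps are
linearly interpolated before decomposition and re-masked afterwards, so the
reconstruction identity (value = trend + seasonal + residual) holds exactly
at every observed point and interpolated points carry no fabricated
residual. `deseasoned_trend()` refits the linear trend on trend + residual
— the seasonally adjusted series rather than the smoothed trend component
alone, so that the significance test keeps the full residual degrees of
freedom; both series are available to the user. Every trend family is
corrected with Benjamini–Hochberg within its own analysis family (e.g. the
regional species tests), not globally across unrelated families.

## The exact partition

Between two windows (defaults: the first and the last 36 months, enough to
balance seasonal coverage in each), per-window species statistics are
cell-weighted: `p̄ᵢ(w)` is species *i*'s share of all cells counted in the
window and `v̄ᵢ(w)` its abundance-weighted mean biovolume, so that
`C(w) = Σ p̄ᵢ v̄ᵢ` is exactly the window's community mean size. With
midpoint (Bennet) weights

$$\Delta C \;=\; \underbrace{\sum_i \tfrac{p̄_i^0 + p̄_i^1}{2}\,(v̄_i^1 - v̄_i^0)}_{\text{within species}}
\;+\; \underbrace{\sum_i \tfrac{v̄_i^0 + v̄_i^1}{2}\,(p̄_i^1 - p̄_i^0)}_{\text{composition}}$$

with no cross term — the identity is algebraic, and the test suite verifies
it to 1e−9 relative on 1000 random instances. A species present in only
one window enters through p = 0 in the other window; its biovolume is
carried over so its within-species term is exactly zero and its whole
contribution is compositional. Stations are then classified with the
two-scenario framework: species sizes declining while Small% is stable or
increasing should produce community miniaturization (scenario i); species
sizes and Small% both declining is the offsetting, uncertain configuration
(scenario ii). The species-level summary is the majority trend class, with
ties resolved to "none".

## Community turnover

Bray–Curtis dissimilarity and the ANOSIM permutation test are implemented
from scratch (mid-ranks for ties, `R = (r̄_between − r̄_within)/(n(n−1)/4)`,
permutation p = (#{R* ≥ R} + 1)/(n_perm + 1)); vegan serves only as an
independent cross-check in the tests. Abundances enter untransformed, as a
single pooled sample × species matrix, and the same matrix is tested
against year, month, station and zone groupings in turn. Permutations
default to 999 with an explicit seed. Two all-zero samples have
dissimilarity 0 by convention (with a warning); a constant dissimilarity
matrix leaves R undefined and is reported missing.

## Driver attribution

* **Correlation screening** computes Pearson r between each (top-abundant)
  species' log biovolume and each environmental factor over matched
  station-months, with support counts; cells with fewer than 3 pairs or
  zero variance are missing with a reason. Hierarchical clustering
  (average linkage, Euclidean distance on correlation profiles, k = 4)
  groups species into temperature/nutrient response types labelled `T±`
  with an `&N±` qualifier when the mean nutrient correlation exceeds 0.1
  in magnitude — the threshold is a visible argument, since response-group
  labels are otherwise a reading of a heatmap.
* **Partial effects** are grouped-intercept least squares:
  `response ~ focal + covariates + station intercepts`. The temperature–
  size rule test applies this per species with log biovolume as response
  and temperature as focal factor; `follows_tsr` means a significantly
  negative temperature coefficient with everything else held constant.
  Fixed grouped intercepts were chosen over a random-effects fit because
  the estimand is the within-group slope of a fixed, small station set;
  the group structure is recorded in the output.
* **The learner tournament** scores any list of `fit/predict` contracts on
  one held-out random split (20 % by default) and picks the winner by
  held-out R², ties resolved by registration order. Five adapters mirror
  the usual model families (ridge, random forest, gradient boosting, small
  neural network, RBF support-vector regression); their internals are
  deliberately off-the-shelf.
* **Shapley values** are computed from scratch under interventional
  semantics: a coalition's value is the mean prediction with absent
  features replaced by background rows (default: 100 rows subsampled with
  a fixed seed — bounded cost, reproducible). Exact mode enumerates all
  coalitions (up to 12 features) with the exact Shapley weights and reports
  the per-sample efficiency residual (below 1e−8). Monte-Carlo mode
  averages marginal contributions over random feature orderings, drawn in
  antithetic pairs (every second ordering reverses the previous one) and
  averaged over the full background set; the error then comes from
  ordering sampling alone and halves as the sample count quadruples. The
  pairwise interaction index uses the Shapley interaction formula over
  coalitions excluding the pair; it is symmetric and vanishes for
  additively separable predictors, and for `f = x₁x₂` with zero background
  it equals the product of the two feature values.

## The synthetic community generator

`scenario_config()` defines the study conditions the validation runs on.
Environment: per-station temperature `T0 + w·t/12 + A·cos(2π(t−φ)/12) + ε`
with warming slopes 0.02–0.06 °C/yr across stations (coastal monitoring
scale, where significant warming up to ~0.06 °C/yr is observed inshore);
phosphate declining ~0.5 μg/L/yr from station baselines of 15–45 μg/L
(floored above zero), DIN and salinity with seasonality and noise only.
Species: lognormal baseline biovolumes spanning roughly 10¹–10⁶ μm³ in
three groups (default pool 25 diatoms / 17 dinoflagellates / 8 others);
per-species temperature–size coefficients β ~ N(−0.025, 0.01) per °C on
log size (centred on the ~2.5 %/°C protist value); intrinsic drifts
γ ~ N(−3e−4, 4e−4) per month (≈ −0.4 %/yr, so that total species-level
decline is of the order seen in decadal records, with interspecific
diversity including stable and growing taxa). Abundances are lognormal
with per-species seasonal phenology of random phase; the composition drift
δ (default −0.003/month) adds `δ·t` to the log abundance of the
bottom-quartile species, making Small% trends monotone in δ by
construction. Blooms multiply one high-weight species' abundance by a
lognormal factor (~10×) in 2 % of station-months — no field bloom-frequency
statistics back these two numbers; they are placeholders for qualitative
realism. A `detect_prob` thins species records to mimic microscopy
occupancy.

The default scenario size (5 stations × 240 months × 50 species) is the
desk-scale validation condition used by the tests and the acceptance
script; `scenario_hk()` scales the same structure to a 25-station,
21-year, 169-species programme.

What the generator does *not* emulate: picoplankton (the size spectrum
below microscopy), mechanistic nutrient–growth coupling, species
interactions, spatial correlation between stations, and observation error
in counts beyond lognormal noise. Passing recovery tests therefore show
the estimators are consistent for this data-generating structure, not that
real monitoring data satisfy it.

## Validation design

* **Recovery study** (`recovery_study()`): the species pool — the injected
  truth — is held fixed while 20 replicate realizations are drawn. The
  regional log-size slope of every species (injected value
  `γ + β·w̄/12`) is re-estimated by OLS; the per-species median over seeds
  must sit within 15 % of the injection (median across species). The sign
  of the regional Small% slope must match sign(δ) in ≥95 % of seeds.
* **Driver recovery**: the species-size model (gradient boosting on
  within-species centred log biovolume — centring removes the 5-decade
  interspecific baseline spread that would otherwise swamp the
  environmental signal) must rank temperature first by mean |Shapley|;
  the Small% model (random forest on station-year means — annual
  averaging removes the seasonal cycle, so the attribution addresses the
  long-term signal, for which declining phosphate is the generator's
  observational proxy of the composition drift) must rank PO₄ in the top
  two, each in ≥90 % of seeds.
* **Type-I error** of the TSR test is measured on a null scenario with
  β = γ = 0 (γ must also be zero because under warming, elapsed time
  confounds temperature for a test that holds only measured factors
  constant, as the field analysis does): 200 seeds × 12 species, pooled
  rejection rate expected at 0.05 ± 0.03.
* **Offset scenario** (`scenario_offset()`): universal species shrinkage
  (γ = −0.001/month) against a strong drift toward large species
  (δ = −0.008/month). The calibration is analytic: with a bottom-quartile
  abundance share a₀ ≈ 0.25 the composition term can contribute at most
  −log(1 − a₀) ≈ 0.29 log units over the record, so the within-species
  loss is set to the comparable 0.24. The pipeline must then report
  non-significant community trends at most stations while labelling them
  scenario ii — the configuration in which community-level stability
  masks species-level miniaturization.

Problem sizes throughout (1000 partition instances, 20 recovery seeds, 200
null seeds, 5 offset replicates, 999 or fewer permutations) were chosen so
the whole validation runs comfortably on a single CPU while keeping
Monte-Carlo noise well inside the test tolerances.

## Known limitations

* ANOSIM permutations are plain R loops; for records much beyond ~2000
  samples the permutation count should be reduced or the samples
  aggregated.
* OLS inference ignores residual autocorrelation; the seasonally adjusted
  cross-check addresses the annual cycle, which is the dominant structure
  in monthly plankton series, but not slower autocorrelation.
* Exact Shapley enumeration is exponential in the feature count; beyond 12
  features use Monte-Carlo mode.
* The quartile rule makes the small-species set depend on the observed
  species pool, so Small% values are comparable only within one analysis.
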