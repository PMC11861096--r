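---
title: "Methods: thermal time, heat stress, and G×E analysis in thermet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal time, heat stress, and G×E analysis in thermet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermet)
```

This vignette is the package's own account of its models and the design
choices behind them: the degree-day conventions, the synthetic trial
generator and what it does (and does not) emulate, the estimators used for
the genotype-by-environment (G×E) analyses, and the numerical conventions
that make results deterministic.

## Thermal time

A day's growing-degree-day contribution is the capped mean of the daily
extremes above a base temperature:

$$\mathrm{dd} = \max\!\left(0,\; \frac{\min(T_{max}, T_{ceil}) + \max(T_{min}, T_{base})}{2} - T_{base}\right),$$

accumulated over calendar windows. Defaults are $T_{base} = 10$ °C and
$T_{ceil} = 30$ °C, the usual cardinal temperatures for chickpea: below 10 °C
development effectively stops, above 30 °C extra heat no longer accelerates
it and instead becomes stressful.

**Capping rule.** The default, `cap_max_floor_min`, caps $T_{max}$ at the
ceiling *and* floors $T_{min}$ at the base before averaging — the common
agronomic convention, and the one consistent with a mild temperate early
sowing accumulating essentially zero stress. The `cap_max_only` variant
(cap $T_{max}$, leave $T_{min}$) is available because some degree-day
traditions use it; both clamp the final day at zero. The choice matters on
days straddling the base: (35, 4) scores 10 under the default but 7 under
`cap_max_only`.

**Stress degree days.** SDD isolates supra-optimal heat by differencing two
accumulations that differ only in their ceiling:

$$\mathrm{SDD} = \mathrm{GDD}_{50} - \mathrm{GDD}_{30}.$$

The 50 °C stress ceiling is deliberately above any temperature a field site
records, so the subtraction captures *all* heat above 30 °C. Because the
50 °C contribution dominates the 30 °C contribution day by day, SDD is
non-negative for every window, and it is exactly zero when no day exceeds
the growth ceiling.

**Stage windows.** Stages are disjoint and additive: vegetative is
`[sowing, flowering − 1]`, reproductive `[flowering, maturity]`, and the
full season their union. `age_days` is defined as the number of calendar
days in the window (so vegetative + reproductive = full season and
`grow_days ≤ age_days` always holds). "Grow days" are days with strictly
positive degree-day contribution; the alternative reading — days whose mean
lies inside `(base, ceiling)` — was rejected because it makes the count
non-monotone in the ceiling.

**Gaps.** Missing dates inside a requested window raise an error naming the
first missing day. Silent interpolation would corrupt cumulative sums, and
a user who wants gap-filling should do it explicitly upstream.

## The synthetic trial generator

The generator emulates the structure of a two-location, two-sowing-time
heat-stress screen of an elite chickpea panel: 148 genotypes (10 desi, 138
kabuli; origins Syria 129 / India 10 / Australia 9), randomized complete
blocks of 2 replicates, 8 m² plots, and a second time of sowing (TOS)
delayed by one month at the hot site and two at the temperate site so that
reproduction runs into hotter weather.

**Weather.** Each location is a sinusoidal annual cycle of the daily mean
plus Gaussian noise, with constant diurnal range
(`tmax/tmin = mean ± range/2`). Defaults: a hot tropical site (mean 27 °C,
amplitude 6, range 14, noise sd 1.5 — consistently warm, frequently above
30 °C) and a temperate site (mean 19 °C, amplitude 8, range 14, noise sd
2.5 — cool winters, heat arriving only in late spring). These were chosen
once, as plausible Ord-Valley-like and northern-NSW-like regimes, to create
the contrast the analyses need: several-fold faster thermal accumulation
and an order of magnitude more SDD at the hot site.

**Phenology** is purely thermal: flowering occurs on the first day whose
cumulative GDD from sowing (sowing day included) reaches the genotype's
requirement, maturity likewise. The inclusive convention makes the
accumulated GDD at flowering meet the requirement with overshoot strictly
below one day's contribution, and a zero requirement flowers on the sowing
day. Requirements are genotype attributes (≈ N(400, 40) to flowering plus
N(500, 50) to maturity, in degree-days), sized so both sowings mature well
inside the generated weather horizon at both sites.

**Traits.** Plot yield is

$$y = (\mu_i + e_j + ge_{ij} + b_{jk} + \varepsilon) \cdot \max(0,\, 1 - s_i \, \pi \, \mathrm{SDD}_{ij}),$$

floored at zero: a genotype potential $\mu_i$ (N(1800, 150) g/plot),
an environment effect $e_j$, G×E interaction, block and residual noise, all
scaled by a multiplicative stress term in the genotype's full-season SDD
($s_i$ its heat sensitivity, ≈ N(0.0012, 0.0005) per SDD, truncated at 0;
$\pi$ a global penalty switch). 100-seed weight uses the analogous additive
model with *small* environment, G×E and stress terms
(−0.005 g per SDD). Stress multiplicative on yield, additive and small on
seed weight, reproduces the empirical plasticity contrast — yield
environmentally plastic, seed size genotypically fixed — without asserting
a physiological mechanism. Genotype main effects live in the panel
(potentials, absolute units); `response_model()` holds everything
environmental. Default environment effects (hot +900/+750 g, temperate
0/−400 g; small analogues for seed weight) encode an irrigated, fertile
hot site that yields well *despite* its heat load, and a temperate late
sowing that loses yield — so within the temperate site, SDD and yield are
designed to be negatively associated.

**The random stream** is seeded once per simulation and consumed in a
documented fixed order — weather (location order), panel (if not supplied),
G×E effects, block effects, residuals — so identical seeds give
byte-identical trials.

**What the generator does not emulate.** Photoperiod and vernalization
responses are out of scope, with one visible consequence: because phenology
is purely thermal, cumulative GDD *at maturity* is close to the genotype's
requirement at every site (the hot site exceeds it only through larger
single-day overshoot), whereas real multi-site data show large site
differences in GDD at a given stage because development is also day-length
driven. Heat stress differences between sites and sowings, flowering-date
contrasts, and all within-site analyses are unaffected; but tests assert
"hotter site accumulates more thermal time" over a fixed calendar window,
not at a phenological stage. Spatial field trend (row/range) effects and
genotype-specific maturity drift under stress are also not modelled.
Passing tests therefore demonstrate correctness of the estimators under a
clean RCBD with thermal phenology, not robustness to field spatial
structure.

## Estimators

**Predicted means.** Cells of the G×E table are replicate means after
subtracting estimated block effects (block mean − environment mean). Under
balance this equals the plain replicate mean; it was chosen over a
mixed-model fit (the natural choice when rows and ranges within replicates
need modelling) because the generator produces no spatial structure and the
balanced estimator is exact, transparent, and dependency-free.

**Superiority and stability.** Cultivar superiority follows Lin & Binns,
$P_i = \sum_j (X_{ij} - M_j)^2 / (2n)$ with $M_j$ the environment maximum;
static stability is the across-environment sample variance. Rankings are
ascending (low = better/more stable) with ties broken by genotype id for
reproducibility. For two-environment runs within a location, the
environments are the sowing times.

**GGE decomposition.** Environment columns are centered by their means —
removing the environment main effect, retaining G and G×E — then SVD'd.
Variance percentages use all singular values, so they sum to 100. SVD axis
signs are arbitrary; they are fixed by making the largest-magnitude
*environment* loading on each retained component positive. Score scaling
defaults to the symmetric split ($\sqrt{\sigma_k}$ to each side), with
genotype- and environment-focused alternatives. A zero-variance (degenerate)
centered matrix returns zero scores and a flag rather than an error, so
pipelines over near-constant traits keep running.

**Heritability.** Within each environment, a balanced two-way ANOVA
(genotype + block) gives the method-of-moments components
$\hat s_e^2 = MS_E$ and $\hat s_g^2 = \max(0, (MS_G - MS_E)/r)$, and
$H^2 = s_g^2 / (s_g^2 + s_e^2/r)$. This estimator is equivalent in
expectation to a REML fit under balance, and the truncation at zero is the
usual guard for negative moment estimates. Unbalanced data are rejected
rather than approximated — the moment solution is only valid when every
genotype appears once per block.

**Correlations and trends.** Spearman's coefficient is computed as the
Pearson correlation of mid-ranked data with the t-approximation p-value on
$n-2$ degrees of freedom ($p = 0$ at $|\rho| = 1$); significance tiers cut
at 0.05 and 0.001. Correlations are computed on genotype × TOS predicted
means pooled within a location, matching the unit of the downstream
selection decisions. Inside the batch correlation table, a constant thermal
vector (e.g. SDD identically zero in a mild environment) yields an `NA`
row rather than an error; the scalar `spearman_test()` keeps its strict
contract. Exponential trends $y = a e^{bx}$ are fitted by least squares on
$(x, \log y)$; $R^2$ is reported on the log scale where the model is
linear (configurable to the original scale, which is not invariant and can
be negative for poor fits). The default trend window is the full season,
where cumulative stress differs most between sowing times.

**Percentage convention.** All environment contrasts use
$(\max - \min)/\max \times 100$ — symmetric, bounded in $[0, 100)$ — rather
than the more common $(\max-\min)/\min$ "percent change". This is the
convention under which the motivating trial's reported contrasts are
internally consistent, and `relative_difference()` documents it prominently
to avoid silent misuse.

## Numerical and scale choices

- Dates are `Date`/ISO-8601 throughout; temperatures °C; weights grams;
  yield stored as grams per plot with area, converted to t/ha
  (`g / m² × 0.01`) only for display.
- Degree-day window sums use exact cumulative-sum arithmetic (no
  interpolation); phenology threshold crossings use a `1e-9` degree-day
  slack so exact-equality requirements (e.g. constant 10 GDD/day against a
  multiple of 10) resolve on the intended day.
- Variance-component truncation at zero; heritability errors when both
  components are zero.
- The test suite exercises the full design size where it is cheap (148
  genotypes × 4 environments × 2 replicates ≈ 1200 plots simulate in well
  under a second) and smaller panels (24–40 genotypes) inside repeated
  property checks: 100-series oracle equivalences, 200-trial
  variance-component recovery at the full 148 × 2 design, and 100-seed
  null-calibration runs.

## Known limitations

- No photoperiod/vernalization model (see above); no hourly or
  sine-interpolated degree days — daily extremes only, assumed
  pre-collapsed from sub-daily station records.
- The heritability estimator requires balance; incomplete designs need an
  upstream mixed-model fit that is out of scope here.
- GGE displays stop at two components; no AMMI, which-won-where polygons,
  or confidence regions.
- Correlation tables apply no multiple-testing correction; the tier labels
  are per-comparison.
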