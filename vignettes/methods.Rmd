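---
title: "Methods: characterization factors for trade-driven alien-species impacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterization factors for trade-driven alien-species impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The impact pathway

`invacf` quantifies terrestrial biodiversity damage caused by alien species
that travel unintentionally with transported goods, in the currency of life
cycle impact assessment: a characterization factor (CF) expressing the
potentially disappeared fraction of native species (PDF), integrated over
years, per kilogram of goods moved from an exporting to an importing country.

The CF factorises into three terms:

* a **fate factor** FF (ASF·yr/kg): how much one kg of transport changes the
  *alien species fraction* (ASF — the share of a country's flora that is
  alien) in the importer,
* an **effect factor** EF (PDF/ASF): how much regional PDF changes per unit
  change in ASF, treated as a global constant,
* a **global extinction probability** GEP (dimensionless, per importer): the
  probability that a regional species loss is also a global one.

Regional CF = FF × EF; global CF = FF × EF × GEP. The package treats an
increase in alien species as monotonically related to an increase in
invasive, damage-causing species, so no invasion-stage distinction is made
anywhere in the pipeline.

## Fate factors from a count model

The observable connecting trade to invasions is the number of alien first
records. For each ordered country pair and each 10-year timestep the package
assembles a panel row holding the cumulative transported mass `TR` (kg) at
the decade's last year, the pair distance `D` (km), the exporter's species
pool `S_e` at the decade's first year (natives plus all earlier arrivals —
established aliens can re-export, the *bridgehead* effect), the importer's
constant native richness `S_i`, and the introduction count `AS` attributed
to the pair in that decade. Every country whose pool contained the species
in the year before a first record receives full (unsplit) credit for that
record; a one-year lag avoids crediting same-year circular routes.

Counts are modelled as negative binomial with a log link:

```
AS ~ intercept + b_tr * z(log(1 + TR)) + b_d * D
     + b_se * log(S_e) + b_si * log(S_i)
     + (1 | importer:period) + (1 | exporter:period)
```

fitted by maximum Laplace-approximated marginal likelihood (`glmmTMB`).
Candidate fixed-effect subsets are compared by AICc, with `k` counting the
intercept, slopes, the NB dispersion, and one variance per random-effect
factor; collinearity is screened with Spearman rank correlations at the
|rho| < 0.5 convention.

Transform choices, and why they are not uniform: trade spans ~15 orders of
magnitude, so it enters as `log1p` (zeros exist before trade begins) and is
z-scored, making `b_tr` a per-standard-deviation effect. Species counts are
always ≥ 1, so they enter as plain logs and keep elasticity-style
coefficients; distance stays in km so `b_d` has physical units. The scaling
constants actually applied are stored on the fitted object and re-applied at
prediction time, so any alternative convention is reproducible by passing
explicit constants.

From a fitted model, with `m(TR)` the population-mode expected count (random
effects at zero, so factors generalise beyond training levels; conditional
mode is available behind a flag):

* **average FF** = `[(m(TR_2019) − m(0)) / S_tot] / (TR_2019 / 150 yr)`,
* **marginal FF** = `[(m(TR_2019 + q) − m(TR_2019)) / S_tot] / q`, with `q`
  the mean annual mass of the final decade (kg/yr).

Both denominators are transport *rates* (kg/yr), which is the only reading
that gives the two variants identical units (ASF·yr/kg). `S_tot` is the
importer's natives plus all aliens present by the final year ("all species
present"); a natives-only variant sits behind a flag. Because the fitted
response is concave in `TR` (the exponent on `1 + TR` is far below 1),
marginal FF ≤ average FF for every pair — a tested invariant. Pairs moving
less than 100 kg/yr on the 150-year mean rate are excluded as too uncertain;
the boundary itself is eligible.

## Effect factor from a low-quantile regression

Country-level PDF is the share of assessed native species (amphibians,
birds, mammals in real applications) that are threatened or extinct *and*
decline due to invasive alien species. The denominator admits only species
whose threat severity was assessed (severity ≠ "unknown"); the numerator
requires a threatened Red-List category (VU/EN/CR/EX/EW) plus a threat row
with an invasive-alien code and a declining severity. Data-deficient species
are resolved three ways — only those predicted threatened (`dd_predicted`,
the headline), none, or all — which brackets the numerator and is monotone
by construction.

PDF is inflated by confounding threats (habitat loss, exploitation, ...)
that only ever *add* to it. The package therefore fits the *lower envelope*
of the PDF-vs-ASF scatter: a quantile regression at the 5th percentile
(10th and 15th reported alongside), weighted by log10 of country area since
small-country assessments are noisier (areas under 10 km² get the weight
floor of 1). The slope of that line is the EF.

The weighted check-loss objective is a linear program with two free
parameters, so an optimal vertex interpolates two observations. The solver
enumerates all point-pair basic solutions exactly and verifies the LP
subgradient condition at the optimum; ties are broken deterministically
(smallest loss, then slope, then intercept). The confidence band is a
weighted pairs bootstrap over countries (default 1000 resamples, seeded) —
the band's method is a package choice, as is the explicit invasive-alien
threat-code set (`8.1` plus subcodes by default), which the data preparer
must map.

## Trade back-casting

Physical trade masses are typically observed only for a recent window, while
monetary flows reach far back. For each ordered pair the package fits
`mass = c1·money + c2·money²` with the intercept pinned at zero on the
overlap years, reports R² on centred total sums of squares (so poor fits go
negative), and predicts the pre-window years, clamping negative predictions
at zero. Observed values are never overwritten by predictions. Pairs with
fewer than 3 overlap years are not pooled or borrowed — their history is
zero-filled with a warning, the conservative and auditable choice. Yearly
masses are then cumulated to decade endpoints: 1879, 1889, …, 2019 — 15
steps for the default 1870–2019 period.

## What the synthetic generator emulates

`generate_world()` draws a closed world whose every table feeds the pipeline
and whose ground truth is recorded: countries (log-normal areas, random
centroids, haversine distances), disjoint native ranges (each species native
to exactly one country), growing log-normal trade with money = mass × noisy
price, introduction counts drawn from *exactly* the count model the fitter
estimates (same transforms, same scaling constants — computable up front
because trade is generated before counts), and threat tables that discretise
a planted `PDF = EF·ASF + ε` relation with strictly non-negative,
half-normal ε. One-sided noise is essential: symmetric noise would break the
low-quantile estimand the EF relies on.

Defaults encode the study conditions: the four planted slopes are the
published point estimates for trade, distance, exporter pool and native
diversity; the EF plant is 0.038 PDF/ASF; the effect-factor recovery fixture
uses 140 countries, the sample size of the country-level analysis. Where no
value is dictated, defaults were chosen once for realism and kept: NB
dispersion θ = 1 (moderate overdispersion; the real analysis does not report
one, so it is configurable and echoed in the truth log), random-intercept
standard deviations 0.5 (substantial unexplained country-by-period
variation), an intercept of −7.4 giving sparse counts (mean ≈ 1–2 per
pair-decade, ~44% zeros), 25 countries × 20,000 species, price noise 5%,
half-normal confounder scale 0.03 (other threats add up to ~6 points of PDF,
consistent with PDF magnitudes well under 0.2).

Species realisation prefers never-before-exported natives of the exporter,
which makes exporter attribution unambiguous and lets tests demand *exact*
equality between the generator's latent counts and the panel rebuilt by the
species-flow module; draws that had to fall back on shared species, and
counts truncated by pool exhaustion, are logged in the truth record. First
records carry the year `decade_start + 1`, so pools evaluated at the
decade's first year and candidate checks at `year − 1` both see exactly the
previous decades' arrivals — generator and fitter stay conjugate at decade
resolution. What the generator deliberately does *not* emulate: real
biogeography, commodity structure, spatially explicit ranges, reporting lags
in first records, or taxonomic error. Passing tests demonstrate the
machinery is correct and the estimators recover planted truth; they say
nothing about how well the model describes real trade-invasion data.

## Numerical choices

* Decade endpoints are `start+9, start+19, …`; periods must divide into
  whole decades, otherwise an error names the offending bounds.
* The quantile solver treats residuals within `1e-9` of zero (relative to
  the response scale) as on the line when verifying optimality.
* Distances fall back to great-circle (haversine, R = 6371 km) only when a
  pair is missing from the distance table, and the fallback is flagged.
* The mixed model starts from glmmTMB's defaults and is deterministic given
  the data; non-convergence and boundary (zero-variance) fits are flagged,
  never silent.
* Variance decomposition uses the latent-scale log-normal approximation
  `ln(1 + 1/mu + 1/theta)` for the distribution-specific variance.
* CSV artifacts are written with shortest-round-trip formatting and read
  back with a correctly-rounded parser, so staged and single-run CF tables
  are bit-identical; JSON artifacts carry 17 significant digits.

## Problem sizes in the test-suite and acceptance runs

The suites exercise: likelihood oracle instances of 60 rows with two levels
per random-effect factor (40-node Gauss–Hermite reference); RE-free
coefficient oracles at n = 400–500; planted-coefficient recovery over 20
seeds of 20-country worlds (5,700 panel rows each), judged by Monte-Carlo
standard errors of the seed means; effect-factor recovery over 20 seeds at
n = 140 with a 15% band on the mean slope; and quantile-solver equivalence
against exhaustive search at n ≤ 8 plus an independent simplex
implementation up to n = 140. These sizes were chosen so each claim is
resolved with comfortable statistical margin.

## Known limitations

* Attribution multi-credits every plausible exporter, so attributed totals
  exceed record counts wherever pools overlap; fate factors inherit that
  convention rather than splitting credit.
* The EF is a single global constant; ecosystem-specific susceptibility,
  mechanistic impact pathways and species–area alternatives are out of
  scope.
* Heteroscedasticity of the count model is reported (residual diagnostics
  plot), not corrected; zero-inflation and spatial autocorrelation are not
  modelled.
* Uncertainty is quantified for the EF (bootstrap) but not propagated from
  the count model into CFs.
* Freshwater and marine damage, commodity-level factors and map rendering
  are outside the package's scope.
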