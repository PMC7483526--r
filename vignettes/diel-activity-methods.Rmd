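---
title: "Methods: diel activity analysis of click-minute records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel activity analysis of click-minute records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielPAM)
```

## The problem

Passive acoustic monitoring of odontocetes with click loggers (C-PODs and
similar) yields, after click-train classification, a minute-resolution time
series of click counts. A recurring question for harbour porpoises is how
this acoustic activity is structured over the 24-h day — elevated at night,
peaking around dawn and dusk, modulated by season — and whether abiotic
covariates (lunar phase and illumination, water level) explain any of it.
`dielPAM` implements that analysis as a reusable, fully seeded pipeline:

1. trim minutes around equipment deployment/retrieval events;
2. segment the record into light periods (sunrise–sunset) and dark periods
   (sunset–next sunrise) from an internal solar ephemeris;
3. summarise each period by its **median clicks per minute**, keeping only
   periods with complete data;
4. compare groups of period medians with **label-randomisation tests** on
   the difference in group medians (day vs night; crepuscular vs other
   times; pairwise lunar phases; low vs high water);
5. estimate the **peak clicking time** by treating minute-of-day as a
   circular variable weighted by click counts: mean resultant, Rayleigh
   uniformity test, von Mises maximum likelihood with a CI for the mean
   direction.

Because click-minute datasets of this kind are typically not deposited
publicly, the package ships a synthetic generator
(`simulate_dataset()`) that reproduces the statistical structure such
records have, with the generating truth retained so the pipeline's recovery
properties can be tested end to end.

## Ephemeris

Sunrise and sunset come from the standard NOAA solar-position algorithm
(equation of time and solar declination evaluated at local noon,
refraction-corrected zenith 90.833°). Against an independently implemented
solar calculator the events agree to well under a minute at mid latitudes;
the package's accuracy contract is ±5 min, ample for 1-minute bins and 2-h
crepuscular windows. Under polar day or night the functions return `NA` —
no event time is ever fabricated — and the segmentation refuses to run.

Lunar phase uses the mean synodic cycle (29.530588853 d) anchored at the
published new moon of 2000-01-06 18:14 UTC; the illuminated fraction is
`(1 - cos(phase_angle)) / 2`. True phases drift around the mean cycle by up
to a few hours, which is irrelevant at the resolution of four phase
categories and quarter-width illumination bins. The four categories quarter
the cycle centred on the cardinal phases: new = [7π/4, π/4), waxing =
[π/4, 3π/4), full = [3π/4, 5π/4), waning = [5π/4, 7π/4).

All timestamps are stored in UTC; local civil time uses a single fixed UTC
offset carried by the `site()` (default Kerteminde harbour, 55.45° N,
10.66° E, UTC+2). No daylight-saving logic is applied anywhere, so a given
record always maps to the same local label. The site coordinates are
configuration, not constants.

## Interval conventions and the complete-period filter

Every interval is half-open `[start, end)`: periods tile the analysed span
exactly, a minute belongs to exactly one period, and boundary minutes are
never double-counted. Bins are closed on the left; the last illumination
bin is closed at 1.0; a water level exactly at the split (default 28 cm)
falls in the *high* group.

Minutes absent from a click file are **gaps** (unknown), never zeros —
silence must be an explicit 0. Trimming removes `[deployment,
deployment + 5 min)` and `[retrieval - 2 min, retrieval)`; it only turns
records into gaps, so it is idempotent. A period is *complete* when it is
not clipped by the span edges and has at most `max_missing_minutes`
(default 0) missing minutes; only complete periods enter the tests. Night
covariates are evaluated at the dark-period midpoint (symmetric, and the
natural single representative the analysis needs) and the water covariate
is the median height over the period, matching the pipeline's
median-based summaries.

## Randomisation tests

The test statistic is `median(a) - median(b)` with the usual
order-statistic median. Group labels are reassigned uniformly at random,
preserving group sizes, `B = 5000` times by default. The two-tailed p-value
uses the add-one convention `(1 + #{|null| >= |observed|}) / (B + 1)`, so p
is never exactly zero and the test is valid as a Monte-Carlo test; the
plain proportion is available via `raw_proportion = TRUE` (at B = 5000 the
two differ by at most 2e-4). Pairwise lunar comparisons are reported
without multiplicity correction, and say so in their metadata.

Two implementation routes produce the same null distribution: a direct
shuffle, and — for large pooled samples with few distinct values — a
multivariate-hypergeometric tabulation (the label shuffle of a multiset is
exactly that), which makes year-scale minute-level tests cheap. The route
is selected deterministically from the input size, so a stored seed always
regenerates the identical null.

**A real limitation worth knowing:** medians of integer counts live on a
half-integer lattice. When groups are large and the count distribution is
concentrated, the sample median is almost surely a single lattice point,
the observed difference collapses to 0, and the test becomes extremely
conservative (p = 1). This is a property of median-difference tests on
coarse counts, not an implementation artifact. It is why the crepuscular
comparison defaults to `crepuscular_unit = "daily_median"` (one median per
local date and label): pooling *all* minutes of a year into two groups
(`"minute"`, also available) pins both group medians to the same integer
under any realistic null. It also dictates the regimes in which type-I
calibration checks are informative — see "Problem sizes" below.

## Circular statistics

Each recorded minute contributes its local time of day as an angle
(`2π · minute / 1440`) weighted by its click count, i.e. clicks act as
angular mass. The weighted mean resultant gives the mean direction (the
peak clicking time) and the mean resultant length r̄; the Rayleigh test
uses the standard large-sample approximation
`p = exp(sqrt(1 + 4n + 4n²(1 - r̄²)) - (1 + 2n))`; the von Mises
concentration solves `A1(κ) = r̄` with `A1 = I1/I0`, by bracketed root
finding to `|A1(κ̂) - r̄| < 1e-8`. The CI for the mean direction is the
asymptotic normal interval `μ ± z / sqrt(n_eff · r̄ · κ̂)`; a seeded
bootstrap over minutes (`vonmises_bootstrap_ci()`) provides an independent
cross-check of its width.

The effective sample size of weighted circular data is genuinely unsettled:
clicks within a minute are not independent observations.
`neff_mode = "weights"` (default) uses the summed weights — faithful to
"clicks as mass", but anticonservative if within-minute clicks are highly
dependent; `"minutes"` counts detection-positive minutes instead and is the
conservative choice. The default is stated in every output. No bias
correction is applied to κ̂ by default (`bias_correct = TRUE` enables the
standard small-sample correction).

One geometric fact the pipeline's users should expect: when activity
concentrates symmetrically at dawn **and** dusk, the fitted mean direction
is their bisector — close to solar midnight — even though the intensity
there is at its base level. The apparent "midnight peak" of pooled records
is the merging of the pre-dawn and post-sunset peaks; the
`crepuscular_only` preset demonstrates it, and a mixture-of-von-Mises model
(out of scope here) would be needed to resolve the two modes separately.

## The synthetic generator

`simulate_dataset()` draws a year (configurable) of per-minute counts from
a negative binomial with mean

```
λ(t) = s(date) · [λ_day + (λ_night - λ_day)·1(night)
                  + bump_amp · (g(t - sunrise) + g(t - sunset))]
       · lunar/water multipliers · period effect · bout effect
```

where `g` is a unit-peak von Mises-shaped kernel in minute-of-day distance
(concentration `bump_conc`), and `s(date) = 1 + season_amp ·
cos(2π(doy - doy_peak)/365.25)` peaks in late June (`doy_peak = 175`).
Bumps attach to the *event times*, so their clock position drifts with
season exactly as the real dawn/dusk peaks do. Two behavioural layers make
the counts realistic rather than minute-iid:

* a **per-period lognormal effect** (`period_sd`, default 0.6 log-units,
  mean one, independent across light/dark periods) — night-to-night and
  day-to-day variation in overall activity;
* an **activity-bout process** (`bout_sd` = 0.7, correlation time
  `bout_tau_h` = 3 h, mean-one lognormal AR(1) on a 30-min grid) — bursts
  and lulls within a period.

Without them, per-period medians of several hundred iid counts are almost
surely a single integer and every downstream median test degenerates; with
them, period medians spread the way real behavioural records do. The
default rate scale (day 15 / night 45 clicks·min⁻¹, bumps to ~60) reflects
animals close to the logger and clicking near-continuously; at rates much
below ~20 clicks·min⁻¹ the integer lattice of the medians dominates their
sampling variation and all median-based tests become structurally
conservative — a regime the generator deliberately avoids for its
reference presets.

Water level is a semidiurnal harmonic pair (M2 + S2, the M2 amplitude
weakly modulated ±15 % over the spring/neap cycle — deliberately weak
lunar coupling, as in wind-dominated inner Danish waters) plus a
heavy-tailed AR(1) surge (t₄ innovations), giving quartiles around ±10 cm
with occasional ~±1 m excursions. The default schedule injects a
deployment at the start, 8 mid-record retrievals with 20–60 min on land,
and two multi-day technical outages totalling 7 days; short runs
(< 30 days) get a single deployment. A master seed feeds independent
sub-seeds for clicks, water and gaps, so adding one stream never perturbs
another.

The truth object stores, besides the config, the circular mean direction
of the noise-free intensity over the span (`true_peak_angle`) and the
noise-free night-minus-day median contrast — both derivable from the
config alone, used by the recovery tests.

**Presets.** `strong_diel` (the reference year), `seasonal` (strong
seasonal cycle), `crepuscular_only` (bumps without a day/night offset),
`tiny` (3 days, for examples), and `flat_null`. The null preset keeps
overdispersion, period effects and bouts but removes *all* structure tied
to labels — no diel contrast, no bumps, no seasonal cycle, no covariate
effects — because it exists to check the tests' size under their own null
hypothesis, exchangeability. A shared seasonal trend, though realistic, is
*not* part of that null: it makes both groups time-balanced while
permutation is not, which renders randomisation tests conservative. That
conservatism is real and worth knowing about (the `seasonal` preset will
show it), but a size check run under a violated null would measure the
violation, not the test.

## Problem sizes and numerical choices

The shipped checks use sizes that keep the whole suite within minutes on a
single core while leaving the conclusions clear: type-I calibration with
two groups of 300 negative-binomial counts (mean 60, size 1 — the regime
where the median lattice is fine relative to its sampling sd), 1000
repetitions at B = 500; exhaustive-enumeration comparison at pooled n ≤ 10
with B = 100 000; von Mises recovery over 500 simulations of 2000 draws at
κ = 4; Rayleigh calibration over 500 uniform samples plus a 100 000-draw
Monte-Carlo null at n = 50; 200 simulated null years at B = 500 for the
end-to-end size check; and a full strong-diel year at B = 5000 for the
end-to-end recovery check.

Numerical details: κ̂ is capped (with a warning) when r̄ is within 1e-12 of
1; r̄ = 0 yields an explicit no-fit signal rather than an arbitrary
direction; Rayleigh p-values are clipped to [0, 1] (the approximation can
underflow to 0 for enormous n·r̄²); CI endpoints are reported along the
circle through μ̂, so an interval straddling midnight prints as e.g.
(23:50, 00:09).

## Known limitations

* Randomisation tests on medians of coarse counts are conservative (see
  above); with strongly trended (seasonal) data they are conservative for
  a second, structural reason.
* The crepuscular comparison is date-paired by construction: each date
  contributes one crepuscular and one other-times median, and the two share
  the same periods' behavioural variance. Label randomisation ignores the
  pairing, so the test's true size runs well below nominal (simulations
  under the exchangeable null put it near 0.005 at nominal 0.05). It loses
  no validity — rejections remain trustworthy — but it has less power than
  a paired design would, and its null rejection rate cannot be expected to
  sit at the nominal level.
* The asymptotic CI for the mean direction assumes large effective n; at
  small n·r̄·κ̂ use the bootstrap cross-check.
* The weighted Rayleigh test's `n_eff = sum(weights)` default overstates
  independence when within-minute clicks are strongly correlated; switch
  to `neff_mode = "minutes"` for a conservative read.
* The generator emulates rate structure, not acoustics: no detection
  probability, propagation, or animal movement; recovery results say the
  *pipeline* works, not that any particular field dataset satisfies its
  assumptions.
* The mean-synodic lunar model is adequate for phase categories and
  quarter bins, not for precise almanac times.

## A worked run

```{r example, eval = FALSE}
d <- simulate_dataset(preset_config("strong_diel"))
report <- run_analysis(d$clicks, d$water, d$deployments,
                       analysis_config(B = 5000, master_seed = 1))
print(report)
write_report(report, "report")
```
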