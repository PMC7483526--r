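# dielPAM

Diel activity analysis of passive acoustic monitoring (PAM) click-minute
records.

Click loggers such as C-PODs reduce odontocete echolocation activity to a
minute-resolution count series: clicks detected per minute, year round.
`dielPAM` is for the ecologist who has such a series — typically for
harbour porpoises — and wants to know how acoustic activity is structured
over the 24-h day and whether abiotic covariates explain it. It implements
the full analysis as seeded, reproducible R functions:

* **Preprocessing** — trim minutes around deployment/retrieval events
  (5 min after deployment, 2 min before retrieval), segment the record
  into light (sunrise→sunset) and dark (sunset→sunrise) periods from an
  internal NOAA-style solar ephemeris, keep only periods with complete
  data, and summarise each by its median clicks per minute.
* **Randomisation tests** — distribution-free two-group comparisons on the
  statistic `median(a) − median(b)`, with labels reshuffled `B = 5000`
  times and the two-tailed p-value `(1 + #{|T*| ≥ |T|})/(B + 1)`. Applied
  to day vs night period medians, crepuscular vs other times (2-h windows
  before sunrise / after sunset), pairwise lunar phases (new, waxing,
  full, waning, assigned at the dark-period midpoint), and low vs high
  water (< 28 cm vs ≥ 28 cm).
* **Circular statistics** — minute-of-day as an angle `θ = 2π·m/1440`
  weighted by its click count: mean resultant length r̄, Rayleigh
  uniformity test `p = exp(√(1+4n+4n²(1−r̄²)) − (1+2n))`, von Mises
  maximum likelihood (`A₁(κ̂) = r̄`, `A₁ = I₁/I₀`) and the asymptotic 95 %
  CI for the peak time `μ̂ ± z₀.₉₇₅/√(n·r̄·κ̂)`, with a bootstrap
  cross-check.
* **Synthetic data** — a generator for year-long records with elevated
  night rates, crepuscular bumps locked to the (seasonally drifting)
  sunrise/sunset times, a summer activity maximum, overdispersed and
  bout-structured counts, tide-like water levels, and logger gaps; the
  generating truth is retained for recovery tests.

## Worked example

```r
library(dielPAM)

d <- simulate_dataset(preset_config("strong_diel"))   # a simulated year
report <- run_analysis(d$clicks, d$water, d$deployments,
                       analysis_config(B = 5000, master_seed = 301))
print(report)
```

```
Diel activity analysis report
  complete periods: 705 (350 day, 355 night)
  day/night:   median diff 10.00 clicks/min, p < 0.01
  crepuscular: median diff 15.00 clicks/min, p < 0.01
  lunar phase: pairwise p-values 0.595 .. 1.000 (uncorrected)
  water level: median diff -13.25 clicks/min, p = 0.101
  Rayleigh: r_bar = 0.275, p < 0.01 (n_eff = 20560658)
  peak clicking time: 01:21 local (95% CI 01:21 - 01:22)
```

Reading this: of 731 light/dark periods in the year, 705 had complete
data. Night periods out-median day periods by 10 clicks/min and
crepuscular daily medians beat the rest of the day by 15 clicks/min — both
effects the generator planted, both detected at p < 0.01. Lunar phase and
water level had no planted effect, and none is claimed. The click mass is
significantly non-uniform over the 24-h circle (Rayleigh r̄ = 0.275), with
the fitted peak at 01:21 local time — solar midnight at this site — within
minutes of the generator's true intensity peak, even though the planted
activity concentrates at dawn and dusk: symmetric crepuscular peaks merge
into an apparent midnight peak in a unimodal circular fit.

`write_report(report, "report/")` writes `periods.csv`, `tests.csv` (one
row per test, with the seed that regenerates its null exactly),
`circular_fit.csv` and `hour_month_median.csv` (a 24 × 12 median matrix).
Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --preset strong_diel --out data/ --seed 42
Rscript inst/cli/analyze.R --clicks data/clicks.csv --water data/waterlevel.csv \
    --deployments data/deployments.csv --lat 55.45 --lon 10.66 \
    --utc-offset 2 --B 5000 --seed 1 --out report/
```

## Scope

The pipeline starts from the exported click-minute table; classifying
click trains out of raw logger data (KERNO and friends) is upstream and
out of scope, as are logger calibration, detection-probability modelling
and plotting beyond the tabular hour × month summaries. See
`vignettes/diel-activity-methods.Rmd` for the model details, conventions,
design choices and known limitations.
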