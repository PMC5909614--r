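---
title: "Estimating genotype-specific phenology parameters by database inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genotype-specific phenology parameters by database inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscan)
```

## The problem

Ecophysiological crop models encode a cultivar's behaviour in a handful of
genotype-specific parameters (GSPs). For maize anthesis these are P1 (thermal
time from emergence to the end of the juvenile phase, GDD), P2 (photoperiod
sensitivity, extra days of the photoperiod-sensitive stage per hour of day
length beyond the critical photoperiod), P2O (the critical short day length,
h) and PHINT (the phyllochron interval, GDD per leaf tip). If those numbers
really were properties of the genotype, one could estimate them from
multi-environment anthesis dates and use them for genomic prediction.
`phenoscan` implements the machinery needed to test that premise: a
three-stage anthesis submodel, inversion of observed anthesis dates against a
quasi-random database of simulated dates, explicit accounting of
*equifinality* (how many parameter sets fit a line equally well) and *model
expressivity* (which observation patterns the model can produce at all), and
a crossed random-effects test of whether the estimates are stable across the
set of environments used to obtain them.

## The anthesis submodel

Daily thermal time is `max(0, min((tmax + tmin)/2, topt) - tbase)` with
defaults `tbase = 8`, `topt = 34` degrees C. The classical three-hourly
temperature interpolation of the full crop model is intentionally out of
scope; the daily-mean formula is the documented convention here, and the two
cardinal temperatures can also be scanned as free axes (a six-parameter box)
when the temperature response itself is in question.

Development proceeds through three stages after an emergence lag of 45 GDD
from sowing (the lag is configurable; emergence parameters are treated as
non-genotypic, so it is a single constant):

1. **Juvenile (Stage 1)** — ends the first day accumulated thermal time
   since emergence reaches P1.
2. **Photoperiod-sensitive (Stage 2)** — each day contributes a development
   fraction `1 / (4 + P2 * max(0, daylength - P2O))`; tassel initiation
   occurs when the fractions sum to 1. Under short days the stage therefore
   lasts exactly four days, regardless of P2. Day length is the
   civil-twilight value (sun 6 degrees below the horizon), computed from a
   standard sinusoidal solar declination
   (`-23.45 * cos(2*pi*(doy + 10)/365)`) and the clamped hour-angle formula;
   the declination model is covered by a root-finding oracle test against a
   full solar-elevation calculation (agreement within 0.1 h).
3. **Leaf expansion (Stage 3)** — with `SUMDTT` the thermal time from
   emergence through tassel initiation, the total leaf number is
   `TOLN = SUMDTT / (0.5 * PHINT) + 5` (five embryonic leaves, two new
   leaves per phyllochron). Anthesis falls on the first day thermal time
   since tassel initiation reaches `(TOLN + 0.5) * PHINT - SUMDTT`.

Two readings of the source description are config-selectable:
`stage2_mode = "daily"` (default; daily-rate accumulation) versus `"fixed"`
(duration computed once from the day length at the end of the juvenile
phase), and `sumdtt_from = "emergence"` (default) versus `"end_juvenile"`
for the origin of `SUMDTT`. The defaults are the readings most consistent
with leaf initiation counting from emergence; the alternatives exist for
sensitivity analysis. All dates are whole days after sowing, with no
sub-daily interpolation; a simulation that has not flowered within the
horizon (250 days by default) returns a *did-not-flower* sentinel rather
than an error.

```{r trace}
w <- tibble::tibble(date = seq(as.Date("2006-01-01"), by = "day",
                               length.out = 650),
                    tmax = 30, tmin = 20)
sy <- site_year("DEMO", 20, 0, 2006, 10, w)
simulate_anthesis(sy, cultivar_params(p1 = 170, p2 = 0.5, p2o = 20,
                                      phint = 43))
```

At 17 GDD per day: emergence on day 3, ten more days of juvenile phase, a
four-day Stage 2 (short days), `SUMDTT = 238`, and anthesis 28 days after
tassel initiation.

## The Sobol database and first-best-found inversion

The parameter box is scanned with an unscrambled Sobol sequence (Gray-code
order, Joe–Kuo direction numbers, 30-bit precision, dimensions up to six).
Each axis is snapped to a rounding resolution — 0.01 for P1 and P2O, 0.0001
for P2, 0.001 for PHINT — chosen so the axes carry at most 30,001 / 401 /
20,001 / 45,001 distinct values over their default ranges (P1 150–450, P2O
10–14, P2 0–2, PHINT 25–70). The database stores the simulated anthesis date
for every set x site-year as small integers (sentinel -1) together with the
box, skip and phenology configuration, and is rebuildable bit-identically
from that metadata; content hashes are checked on load.

A line is estimated by scanning rows in generation order, scoring
`RMSE = sqrt(sum((simulated - observed)^2) / n)` over its observed
site-years with exact integer sums of squares. The running best is replaced
only on a *strictly* smaller SSE, so the report is the first-best-found
estimate, and the number of later rows tying the final minimum is the line's
equifinality extent. Rows that did not flower on a scored site-year are
ineligible for that line rather than being penalised with an imputed date —
the conservative choice, since no penalty rule is defined for the model;
ineligibility is reported per line.

The default desk-scale database is $2^{16}$–$2^{18}$ sets; the scan scales
linearly and the study-scale tens of millions of sets are a configuration,
not a requirement.

## Expressivity

For a site-year subset, the achievable set is the deduplicated collection of
simulated anthesis-date tuples over all database rows, each with its first
witness row. A line is *expressible* when its observed tuple matches an
achievable tuple exactly; otherwise it is assigned the nearest achievable
tuple under the RMSE metric (order-equivalent to Euclidean distance for a
fixed subset; ties broken by first-witness order) and inherits the witness
parameters — which is exactly what the database scan reports for such lines,
and is what makes stranded lines share identical estimates ("banding"). In
two dimensions the frontier is formalised as the achievable cells with a
missing 4-neighbour on the integer date lattice; this is one faithful
formalisation of a boundary that, in the source analyses, was drawn by hand
on a scatter.

## Stability of the estimates across environments

If GSPs are genotypic, estimates should not depend on which environments
were used to estimate them. The test enumerates all `choose(n, k)` site-year
subsets (330 for 7 of 11), runs a first-best-found search per (line,
subset), discards searches with ties (equifinality would dilute the test)
and subsets retaining too few lines, and fits by maximum likelihood the
crossed random-effects model

$$\rho_{l,e} = \mu + \alpha_l + \beta_e + \varepsilon_{l,e},\qquad
\alpha_l \sim N(0, \sigma^2_l),\;
\beta_e \sim N(0, \sigma^2_e),\;
\varepsilon_{l,e} \sim N(0, \sigma^2_\varepsilon)$$

with and without the subset effect $\beta_e$. ML (not REML) is used
throughout because the compared models differ in their random structure. The
implementation profiles $\mu$ and $\sigma^2_\varepsilon$ analytically and
optimises the two nonnegative variance ratios, applying the Woodbury
identity on the (lines + subsets)-dimensional inner matrix; boundary
estimates of exactly zero are permitted. Unit tests verify agreement of the
log-likelihood with an independent mixed-model implementation (`lme4`,
ML) to better than 1e-4 on balanced and unbalanced panels.

The LRT for $\sigma^2_e = 0$ is a boundary test. Two null references are
provided and recorded in the output: `half_df`, a central chi-square with
0.5 degrees of freedom (the convention adopted by the source analysis), and
`mixture`, the conventional 50:50 mixture of a point mass at zero and
chi-square(1), reported as $p = 0.5\,P(\chi^2_1 \ge LRT)$ (so a zero
statistic reports $p = 1$ under `half_df` and 0.5 under `mixture`). The two
references differ, which is precisely why the choice is an explicit,
recorded flag. Very large statistics underflow double precision; `log10_p`
then switches to a documented Chernoff bound,
$\log_{10} p \le [\,df \log(x/df) + df - x\,] / (2 \ln 10)$, and the
`p_method` field says which path produced the number. The printed p-value
exponents of the source analysis follow no standard chi-square tail we can
identify, so no attempt is made to reproduce them; the bound above is this
package's own documented convention.

Instability is summarised by the Index of Variability,
$100\,\sigma_e/\mu$, and by the subset share of total variance,
$100\,\sigma^2_e/(\sigma^2_l + \sigma^2_e + \sigma^2_\varepsilon)$.

## The continuous cross-check

`de_search()` fits a single line by differential evolution (rand/1/bin,
population 60, F = 0.7, CR = 0.9, up to 500 generations with a
spread-based stop — all configurable; the source analysis states none of
these, so they are this package's defaults) over a deliberately extended box
(P1 75–600, P2O 6–21, P2 0–6, PHINT 20–100). The initial population is a
Sobol design over the bounds, which guarantees by elitism that the result is
never worse than a quasi-random scan of the same size. The objective is
piecewise constant (integer dates), which DE handles without modification.
The scientific use of the cross-check is negative: even with much wider
ranges and a continuous search, inexpressible observations remain
inexpressible.

## The synthetic study

No field data ship with the package. `make_synthetic_study()` generates a
panel with the structure of the multi-site maize NAM trials: 11 site-years
at latitudes 18.00–42.73 N with sowing days of year from 120 to 314
(spring sowings in the north, late-year sowings in the tropics), weather as
an annual sinusoid plus Gaussian noise (site mean and amplitude follow a
simple latitude gradient: mean tmax `36 - 0.3 * lat`, amplitude
`0.35 * lat`, diurnal range 10 C, noise sd 2 C — plausible growing-season
magnitudes, not a climate model), 600 lines with true parameters drawn
uniformly in the box, observation noise applied as a rounded Gaussian with
sd 1.5 days (anthesis is scored in whole days), and independent 15%
missingness; lines whose simulation fails at a site-year are missing there.
An optional per-site-year bias (in days) emulates environment-dependent
structural error, which is the mechanism that makes estimates genuinely
unstable and gives the stability test something real to detect.

What the generator does *not* emulate: family structure of the mapping
population, spatial field effects, observer effects, weather measurement
error, or any correlation between noise and environment. Passing tests
therefore demonstrate the estimation machinery's internal correctness and
calibration — closed-loop identifiability, equifinality trends, test
calibration and power — not the field behaviour of real trials.

## Numerical choices and problem sizes

- Exact integer arithmetic everywhere ties are decided; no floating-point
  equality in the tie logic.
- Stage-2 completion uses a 1e-12 tolerance on the accumulated fraction so
  that an exact four-day sum is never missed to rounding.
- Sobol axis values are re-rounded to the decimal scale of the resolution,
  so CSV round trips are bit-identical.
- The variance-ratio optimiser is bounded quasi-Newton from a 0.5 start
  with a derivative-free polish; boundary solutions are legitimate and the
  deviance returns a large finite penalty (not Inf) on degenerate
  evaluations.
- Default problem sizes are chosen for minutes-scale runs on one CPU:
  databases of $2^{12}$–$2^{16}$ sets, hundreds of lines, 200-replicate
  calibration studies on 200 x 50 panels. All are configuration, and the
  vignette-scale defaults understate the equifinality a study-scale database
  would reveal (a denser scan can only add ties).

## Known limitations

- The emergence lag and cardinal-temperature defaults of the original
  model version are not documented in the source; they are configurable
  and recorded in every run manifest.
- The photoperiod model is astronomical; no weather-dependent twilight.
- The stability test assumes independent Gaussian effects; overlapping
  subsets share site-years, so subset effects are in truth weakly
  dependent — a caveat inherited from the design it reimplements.
- `stage2_mode = "fixed"` and the alternative `SUMDTT` origin are
  sensitivity switches, not calibrated alternatives.
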