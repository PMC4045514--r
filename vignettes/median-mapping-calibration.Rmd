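---
title: "Median-mapping calibration of bone age scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-mapping calibration of bone age scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneagecal)
library(dplyr)
library(ggplot2)
```

## The problem

Bone age (BA) ratings inherit the reference population of the rating
system. A Greulich-Pyle (GP) bone age of 13.5 years means "as mature as
the average 13.5-year-old in the GP atlas's 1930s American reference
group". When the target population matures on a different schedule —
modern Chinese urban children, for instance, finish maturation about a
year earlier than that reference — the rating remains a perfectly good
*maturity measure* but becomes a misleading *age scale*. The same
applies to the Tanner-Whitehouse (TW) Sum Maturity Score (SMS), a
weighted sum over 13 RUS bones that runs from early childhood to a
ceiling of 1000 at full maturity.

This package constructs population-adapted scales from a
cross-sectional cohort of rated radiographs by **median mapping**, and
provides the surrounding machinery: reference curves, the published
BX-China05 / TW-China05 tables, rater-agreement statistics, and a
synthetic-cohort generator that makes every stage testable without
access to radiographs.

## The model

Write $T(a)$ for the population median of the maturity measure at
chronological age $a$. The population bone age assigned to an observed
value $g$ is

$$ \mathrm{BA}_{\mathrm{pop}}(g) \;=\; T^{-1}(g), $$

the age at which the population median equals the observation. If the
median GP BA at age 13 is 13.5 years, then a child rated 13.5 is
exactly as mature as the median 13-year-old, so their population bone
age is 13.0 years. The construction has three steps, each a separate
exported function so intermediate objects can be inspected:

1. **Tabulate** (`median_by_age()`): the interpolated sample median of
   the measure at each grid age, using the records whose chronological
   age is closest to that grid age (see *Binning* below).
2. **Monotonize** (`monotonize()`): sampling noise can make adjacent
   medians invert locally, while inversion presumes a non-decreasing
   $T$. We replace the medians by their least-squares isotonic fit via
   pool-adjacent-violators (`stats::isoreg`). On already-monotone
   input this is the identity; it never changes the age grid.
3. **Invert** (`invert_to_bone_age()`): piecewise-linear interpolation
   on the tabulated $(T(a), a)$ pairs. Flat segments — exact ties
   created by the isotonic fit — map to the midpoint of the tied age
   range, the symmetric choice. Observations outside the tabulated
   median range clamp to the first/last grid age and are flagged
   (`out_of_range` attribute plus a warning): the automated rating
   methods themselves become unreliable near full maturity, so silent
   extrapolation would be clinically misleading.

Two applicable forms are emitted. A GP-style scale becomes a
**correction table** (`build_correction_table()`): corrections
$c(g) = \operatorname{round}_{0.1}(T^{-1}(g) - g)$ on a 0.5-year grid
of observed GP BA from 2.0 years up to the top tabulated median, the
last row carrying "and above" semantics. An SMS-based scale becomes an
**anchor table** (`build_sms_scale()`): pairs (bone age = grid age,
SMS = monotonized median SMS), with the terminal anchor placed exactly
at SMS 1000 at the age where the fitted median first reaches 1000
(linear continuation of the last segment if the ceiling is never
sampled). Application (`bx_china05()`, `tw_china05()`) interpolates
linearly between rows/anchors, reproducing the printed values exactly
at grid points.

### Properties maintained by construction

* Pre-rounding, $g + c(g) = T^{-1}(g)$ exactly, and $g + c(g)$ is
  non-decreasing in $g$ (inversion of a monotone curve); after
  rounding to 0.1 years it can step down by at most one rounding unit.
* `maturity_to_sms()` (the generator's age-to-SMS map) and
  `tw_china05()` interpolate the same anchors in opposite directions,
  so they are exact mutual inverses on the anchor range — the
  round-trip is tested to $10^{-9}$.

## Binning and grids

The emulated study design samples children *at their anniversaries*
(ages 2–20), with two extra sampling points at 2.5 and 3.5 years.
Reference curves (`ba_minus_ca_curve()`) use half-open 1-year bins
centered on the anniversary grid, $[a - \tfrac12, a + \tfrac12)$, so
each bin owns exactly one anniversary; bins with fewer than `n_min`
(default 10) records are dropped rather than zero-filled, because tiny
extreme-age bins would otherwise produce unstable ±2 SD bands. The SD
is the sample SD ($n-1$), and `average_sd()` quotes the unweighted
mean of per-bin SDs over a closed age interval — the convention for
summarizing an SD curve computed in 1-year intervals.

For the *median* tabulation the half-year sampling points matter: with
plain 1-year bins the 2.5-year records fall into the bin centered at
3 and the 3.5-year records into the bin centered at 4, dragging those
medians down by visibly more than the sampling error (we measured a
bias of about 0.2 years at the 4-year grid age in a cohort of 1000 per
age). `median_by_age()` therefore assigns each record to its *nearest*
grid age (never farther than `bin_width/2`, ties going up), and the
default grid is the full sampling design
`anniversary_ages()` = {2, 2.5, 3, 3.5, 4, …, 20}. On a uniform grid
this reduces to exactly the half-open-bin convention; on the default
grid it keeps the half-year points as their own tabulation ages —
which also matches the published TW-style anchor tables, whose anchor
set has rows at 2.5 and 3.5 years. Half-year rows of a correction
table between anniversaries are served by interpolation of the
inverted curve, not by separate half-year bins: anniversary sampling
gives no data there.

## The synthetic-cohort generator

`simulate_cohort()` emulates the cross-sectional design the analysis
assumes. For each sex, sampling age $a$, city and replicate:

$$ ca = a + \eta,\qquad gp\_ba = ca + f_{\mathrm{sex}}(ca) +
   s_{\mathrm{city}} + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma). $$

* $f_{\mathrm{sex}}$ is a piecewise-linear **maturation offset curve**
  (`offset_curve()`): mean BA − CA versus age. The defaults are zero
  through childhood, ramping through puberty to a plateau of +1.0
  years (boys: knots at 2, 8, 13, 16, 20 years with offsets 0, 0, 0.5,
  1.0, 1.0; girls the same shape shifted one year earlier), matching a
  population that reaches full maturity about a year before the GP
  reference.
* $s_{\mathrm{city}}$ is an additive city shift. The default five
  cities span −0.3 to +0.3 years, the simplest structure consistent
  with roughly parallel per-city mean curves, with the most advanced
  and most delayed city 0.6 years apart.
* $\sigma$ (`residual_sd`, default 1.1 years) is the individual
  scatter of BA − CA, in the 1.1–1.3-year range reported for pooled
  multi-city cohorts.
* $\eta$ (`age_jitter_sd`, default 0.05 years) models "close to the
  anniversary" sampling: near-discrete ages keep binning unambiguous
  while avoiding degenerate exact ties.

SMS values are generated by pushing an *independently* noised TW-scale
bone age (same offset structure, its own $\varepsilon$) through the
strictly increasing age-to-SMS map `maturity_to_sms()` and rounding to
the integer scores raters report; routing SMS through its own bone age
rather than through `gp_ba` keeps the GP and TW calibrations from
being trivially redundant copies of each other. Optionally a manual
TW3 re-rating is emulated as the automated rating minus
$N(\text{bias}, \text{sd})$ with sex-specific defaults (bias 0.00 /
−0.37 years, sd 0.64 / 0.57 years, chosen so automated-minus-manual
differences have rms 0.64 / 0.68 years), giving realistic Bland-Altman
input. One seed drives the whole cohort; the caller's RNG stream is
left untouched.

What the generator deliberately does **not** model: radiograph images
and image-quality failures, within-city social-class structure (only a
single residual SD), secular trends over calendar time, non-Gaussian
individual variation, and rater behavior beyond an additive
bias + noise. Consequently, passing recovery tests show that the
pipeline's *estimators* are correct under the design assumptions — not
that any particular real population satisfies those assumptions.

## Agreement analysis

`pair_ratings()` builds per-image pairs with mean
$\mathrm{mid} = (a+b)/2$ and difference $d = a - b$ (convention:
automated minus manual, which makes a manual rater who rates *higher*
show up as negative bias). `bias_rms()` reports the mean difference
and the root-mean-square deviation about zero over a stated mid range,
using the $n$ denominator — an rms, not a variance estimate — so
$\mathrm{rms}^2 = \mathrm{bias}^2 + \mathrm{Var}_{\mathrm{pop}}(d)$
holds as an algebraic identity (tested to $10^{-12}$). The
running-average curve is a boxcar mean (default window 1.0 years) on a
0.25-year grid, omitting points supported by fewer than 5 pairs.

## Numerical choices and degenerate inputs

* Corrections are rounded to 0.1 years via `round(x / 0.1) * 0.1`
  (R's round-half-to-even at exact .05 boundaries, which the
  tabulated medians essentially never hit).
* Records are assigned to the upper bin when exactly on a bin
  boundary (half-open intervals), so jittered ages are handled
  deterministically.
* An empty cohort cannot be written; a curve with every bin below
  `n_min` raises a typed error rather than returning an empty table;
  fewer than two surviving median grid ages aborts calibration.
* Medians use R's default interpolated sample median (type 7):
  $\{1,2,3\} \mapsto 2$, $\{1,2,3,4\} \mapsto 2.5$.
* SMS values outside $[0, 1000]$ are rejected at I/O, generation and
  application time; 1000 is a hard ceiling, not a clampable value.

## Problem sizes in the test suite

The recovery tests run at desk scale: parameter recovery uses 1000
records per age and sex (≈ 42,000 rows) and checks every interior
correction against the injected offset within ±0.15 years — about
three median standard errors ($1.2533\,\sigma/\sqrt{n} \approx 0.044$
years) plus the 0.05-year rounding half-unit; zero-offset
self-consistency and SD recovery use 2000 per age. At those sizes the
whole suite runs in well under a minute.

## Known limitations

* The cohort-dependent numbers of the original Chinese study (per-bin
  SDs, rater bias/rms, rating efficiency) require the real radiograph
  ratings, which were never deposited; the package ships the study's
  *resulting tables* as data and verifies the *procedure* on synthetic
  cohorts instead.
* Correction tables are emitted unsmoothed: each grid row reflects the
  inverted median curve at that value only. Published tables may have
  been hand-smoothed; small row-to-row wiggles (one rounding unit) are
  therefore expected when comparing a fresh calibration against a
  printed table.
* No smooth centile estimation (LMS, quantile regression): reference
  bands are plain binned means ± 2 SD, which is what the median-
  mapping construction needs and nothing more.
* Below-range behavior (GP BA under 2.0 years, SMS under the first
  anchor) is a clamp-with-flag convention; the underlying methods are
  simply not defined there.
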