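---
title: "Personalized reference intervals, reference change values, and longitudinal flagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized reference intervals, reference change values, and longitudinal flagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prri)
```

## The model

A laboratory measurand in an individual at steady state is modelled as
fluctuating multiplicatively around a homeostatic set point (HSP): an
observed result is

$$x = \mathrm{HSP}\cdot(1 + e_P)\cdot(1 + e_A),$$

with within-person biological noise $e_P$ of coefficient of variation
$CV_P$ and analytical noise $e_A$ of coefficient $CV_A$, independent
between results. Two consequences drive everything in this package:

1. An individual's steady-state results have total variation
   $CV_T = \sqrt{CV_P^2 + CV_A^2}$, estimated as $100\cdot SD/\bar x$
   from a history of $n$ results.
2. The population-level within-subject variation $CV_I$ (the average
   $CV_P$ over a reference population, as curated in biological-variation
   databases) can stand in for $CV_P$ when an individual's history is too
   short to estimate it.

A *personalized reference interval* (prRI) is the region around the HSP
expected to contain steady-state results at coverage $1-\alpha$. Because
the HSP itself is estimated by the mean of $n$ results, a fresh result
differs from that mean with variance inflated by $(1 + 1/n)$; the
small-sample factor $\sqrt{1 + 1/n}$ therefore appears in both routes:

- **Population route** (`prri_pop`), normal quantile $z$:
  $\mathrm{HSP} \pm z\,\mathrm{HSP}\,\frac{\sqrt{CV_I^2+CV_A^2}}{100}\sqrt{1+\tfrac1n}$
- **Individual route** (`prri_ind`), Student quantile $t_{n-1}$:
  $\mathrm{HSP} \pm t_{n-1}\,\mathrm{HSP}\,\frac{CV_T}{100}\sqrt{1+\tfrac1n}$

The individual route substitutes an estimated dispersion for a known one,
which is what the $t$ quantile accounts for; at large $n$ with
$CV_T = \sqrt{CV_I^2 + CV_A^2}$ the two routes coincide (a tested
property). At $n = 3$, $t_2 = 4.30$ versus $z = 1.96$, so short histories
inflate the individual route by more than a factor of two — the central
practical caveat, and the reason `check_applicability()` recommends the
population route below 5 history points.

The *reference change value* (`rcv_pop`, `rcv_ind`) is the delta-check
threshold for two consecutive results: each carries the full noise, so
their difference has $\sqrt2$ times the single-result CV, giving
$RCV = z\sqrt2\,CV$ with $CV = \sqrt{CV_I^2+CV_A^2}$ or $CV_T$. The
individual basis already contains the analytical component inside
$CV_T$; no further $CV_A$ term is added.

The *index of individuality* $II = CV_I/CV_G$ (with $CV_G$ the
between-subject variation of set points) quantifies when popRIs are
useful at all: below about 0.6, individuals occupy narrow bands inside a
wide population interval and population limits are insensitive for
monitoring. A noise-adjusted variant
$\sqrt{CV_I^2+CV_A^2}/CV_G$ is provided; the simple ratio is the default
as the more commonly used form.

### Assumptions

Gaussian multiplicative noise on the CV scale; independence between
results (no autocorrelation); a constant HSP during the steady-state
window (steady state is not the same as healthy — a stable chronic
abnormality satisfies it); CVs small enough that the normal
approximation of multiplicative noise holds (at $CV\gtrsim 30\%$ the
intervals lose meaning, which is one of the applicability rules).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `coverage` | 0.95 | probability | conventional central-95% reference limits; quantiles kept at full precision (1.959964, not 1.96) so that published 2-decimal values recompute exactly |
| `n` (history size) | — | count | taken from the HSP history; enters both the $\sqrt{1+1/n}$ factor and the $t$ degrees of freedom |
| `clamp` | `FALSE` | — | negative computed lower limits are reported as-is (transparent arithmetic) though concentrations cannot be negative; `TRUE` truncates at 0 and marks the interval |
| `strict` (flagging) | `TRUE` | — | values exactly at a limit, and changes exactly at the RCV threshold, are in range; configurable |
| `rcv_reference` | `"previous"` | — | percent change relative to the earlier result (delta-check convention); `"mean"` offered |
| applicability cut-offs | $CV_A \le 0.5\,CV_I$, $CV_I \le 30\%$, $n \ge 5$ | — | accepted suitability rules for BV-based personalized intervals |

## Display rounding and comparison conventions

Internal arithmetic never rounds; display rounding is half-up (half away
from zero) via `round_half_up()`, matching laboratory reports rather than
base R's round-half-to-even. When recomputed values are compared against
the packaged case table (`reproduce_table1()`), a cell agrees if it
matches within one unit of the last printed digit — published tables are
computed from unrounded raw data, so the printed inputs can shift the
last digit by one — and printed strings ending in a zero are also
accepted at one fewer decimal, because the source table's rounding
convention is not uniform (some limits are 2-decimal values padded to
three). The agreement report is explicit about cells that cannot
agree: a set point printed as 0.1 when the unrounded value was ≈0.08
propagates a large relative error into every derived cell of that row,
and one RCV cell is not reproducible from its own printed CVs. Those
stay flagged as disagreements rather than being absorbed into tolerance.

## Degenerate inputs

- $CV_T = 0$ (a zero-spread history, typical for a measurand reported
  with one significant digit): the individual-route interval collapses to
  a point and the RCV to 0%; both are returned as computed, carrying a
  machine-readable not-applicable marker plus a warning, rather than
  erroring.
- $CV_A > CV_T$: $CV_P$ would be imaginary; `cv_within_person()` returns
  0 with a warning (sampling noise, not a model violation).
- A zero earlier value in a delta check makes the relative change
  undefined: the pair is skipped with a warning and excluded from the
  flag counts.

## The flagging pipeline

`flag_series()` evaluates a day-indexed series under up to five criteria
(popRI, both prRIs, both RCVs); `summarize_flags()` pools counts across
measurands into per-criterion `k/N` ratios. Two conventions matter and
are pinned as defaults: RCV flags are attributed to the *later* point of
each consecutive pair but reported against the full point count (so an
11-point series contributes 11, not 10, to every criterion's
denominator — the convention used when comparing criterion sensitivity on
a fixed panel), and all inequalities are strict. Missing values are
excluded from numerator and denominator with a message.

## What the simulator emulates — and what it does not

`simulate_panel()` generates the exact structure the analysis assumes:
multiplicative Gaussian (optionally log-normal) steady-state noise with
per-measurand $CV_P$ and $CV_A$, an HSP history of configurable length,
and pathological episodes as piecewise-constant fold-change windows
(optionally linearly ramped) on the day grid, with truth labels per
point. `default_sim_config()` mirrors the packaged case geometry: 10
CBC/differential measurands × 11 days from Day −10 to Day 115 around a
symptom-onset Day 0 (110 results), history n = 3, set points and noise
levels from the case table, and an acute window (Day 0–14) with
fold-changes typical of a mild viral infection — neutrophils 1.8,
monocytes 1.6, leukocytes 1.5, lymphocytes 0.55, eosinophils 0.4, red-cell
measurands unchanged. These folds are a fixed modelling choice for a
plausible episode, not a fit to any dataset.

The simulator does **not** reproduce: autocorrelation between visits
(real series at irregular spacing are likely correlated), inter-measurand
correlation (leukocytes are the sum of the differential counts; draws
here are independent), instrument drift, or pre-analytical artifacts.
Passing tests therefore validate the *arithmetic and the flagging logic*
under the model's own assumptions — they show the intervals have the
nominal properties when the model holds, not that the model holds for
any particular patient.

## Validation design and problem sizes

The test suite checks every formula against independently re-coded
brute-force algebra on randomized inputs (relative tolerance $10^{-10}$),
and the following statistical properties at these scales, chosen so the
Monte-Carlo error is far below each tolerance while the suite stays
quick: interval symmetry and width monotonicity over randomized
parameter draws; $t\to z$ route agreement at $n = 10^6$ (relative
difference $< 10^{-3}$); sample-CV recovery of
$\sqrt{CV_P^2 + CV_A^2}$ on a $10^5$-point steady-state panel (within
1%); and coverage of the population-route interval on fresh steady-state
points within 3 Monte-Carlo standard errors of 95% over 1000 replicates
of (history of 3) × (20 scored points). Flag counts on the synthetic
110-result panel are checked against point-by-point enumeration for all
five criteria.

## Known limitations

- Symmetric normal-theory intervals only; log-normal/asymmetric RCVs and
  one-sided variants are out of scope.
- $CV_G$ is needed only for the index of individuality; when it is
  back-derived from a published II it inherits that value's rounding.
- The individual route at $n = 3$ is reported because it is part of the
  method surface, but its width makes it clinically unhelpful there —
  the applicability verdict says so rather than suppressing it.
- Published tables computed from unrounded raw data can be reproduced
  only to within one unit of the last printed digit; the package keeps
  full precision internally and treats printed values as display output.
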