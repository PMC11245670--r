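---
title: "Scoring lifetime resilience and quantifying in-utero stressor effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lifetime resilience and quantifying in-utero stressor effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilherd)
```

## The problem

Dairy-cow resilience — the capacity to complete many lactations with good
fertility and few health problems under whatever management and environment a
farm provides — is increasingly used as a selection and management target.
One strand of evidence suggests resilience is partly set before birth:
stressors experienced by the dam during gestation (disease, treatments,
thermal discomfort) may program the developing calf. `resilherd` provides the
full analysis chain needed to quantify such associations from routine herd
management exports: a lifetime resilience score (LRS), thermal-exposure
assessment over gestation windows, record cleaning and pedigree pairing,
lactation-curve fitting, and hierarchical mixed models with stepwise
selection — plus a synthetic-herd generator with known ground truth so every
stage is testable without access to any proprietary herd database.

## The lifetime resilience score

For cow $i$ exiting in lactation $L_i$, with age at first calving
$\mathrm{AFC}_i$ (days), calving intervals $\mathrm{CInt}_{i,j}$ and daily
milk yields $\mathrm{MY}_{i,j,k}$ (kg at day $k$ of lactation $j$):

$$
\mathrm{LRS}_i = \overline{\mathrm{CInt}} + 300\,L_i + (730 - \mathrm{AFC}_i)
+ \sum_{j=1}^{L_i-1}\left(\overline{\mathrm{CInt}_j} - \mathrm{CInt}_{i,j}\right)
+ \sum_{j=1}^{L_i}\left[\frac{\sum_{k=1}^{K_j}\mathrm{MY}_{i,j,k}}
{\sum_{k=1}^{K_j}\overline{\mathrm{MY}_{j,k}}} - 1\right] \times 100
+ \min\!\left(0,\ \mathrm{DIM}_{i,L_i} - 100\right),
$$

with $K_j = \max(305, \mathrm{DIM}_{i,j})$ and overbars denoting herd
averages over all selected cows and years. Every cow therefore starts from
the herd-mean calving interval, earns 300 points per started lactation, and
gains or loses points for calving earlier or later than 730 d, for
shorter-or-longer calving intervals relative to the herd's per-transition
means, for percentage 305-d yield deviation from the herd, and pays up to
99 points if she exits before 100 days in milk. `compute_lrs()` stores the
six additive components separately and their sum is the score exactly.

Two notational points are resolved deliberately:

- The displayed yield-term denominator is the *herd-average* daily-yield sum
  (the verbal definition: the percentage that yield is above or below the
  herd average); implementing it as a copy of the numerator would make the
  term identically zero.
- Daily yields come from fitted lactation curves on both sides of the ratio,
  because monthly recording cannot supply daily sums. Herd daily means
  $\overline{\mathrm{MY}_{j,k}}$ are across-cow means of fitted curves.

A cow whose every input sits at the herd average scores exactly
$\overline{\mathrm{CInt}} + 300 L_i$; this identity, the 730-d zero crossing,
the strict-below-100 penalty onset and a hand-computed 1,020-point example
are frozen as analytic tests.

## Lactation curves and 305-d yield

Each cow-lactation is fitted with the four-parameter MilkBot curve

$$ y(t) = a\left(1 - \tfrac{1}{2}e^{(c - t)/b}\right)e^{-dt}, $$

where $a$ is the scale (kg), $b$ the ramp (d), $c$ the offset (d) and $d$
the decay (1/d). Fitting is bounded Levenberg–Marquardt least squares on
recordings with DIM in [0, 305] and yield > 0; start values are data-driven
(scale near 1.2× the maximum recorded yield, ramp 25 d, offset −5 d, decay
0.002/d) with three jittered restarts, because nonlinear fits on ~10 monthly
points are fragile. Fewer than four usable points flags non-convergence, and
the default policy drops such cows from scoring (their count is reported);
predictions are floored at 0 kg and the 305-d yield is the literal sum of
predicted daily yields over days 1–305.

## Thermal exposure

Daily station summaries supply maximum temperature $T$ and dewpoint $DP$
(both °C). Minimum relative humidity uses the Magnus form
$\mathrm{RH} = 100\, e^{17.625\,DP/(243.04+DP)} / e^{17.625\,T/(243.04+T)}$,
and the maximum temperature–humidity index is
$\mathrm{THI}_{max} = 0.8\,T + (\mathrm{RH}/100)(T - 14.4) + 46.4$.
Records with $DP > T$ are physically inconsistent; RH is clamped to 100 and
the occurrences counted. Station-years missing more than 10% of calendar
days (leap years handled) are excluded in multi-herd mode; the single-herd
mode keeps them flagged, matching the situation where the only nearby
station has a gappy year. Farms are matched once to their nearest QC-passing
station by haversine distance on a spherical Earth; window means simply
average the days available inside the closed date interval. Which dewpoint
summary (mean vs minimum) pairs with the daily maximum temperature is taken
as given by the input column; the formulas are agnostic to that choice.

## Gestation windows and features

Conception is estimated as calving − 283 d (or the recorded last
insemination in research-herd mode). Days relative to conception map to
three windows — T1: −7..94, T2: 95..189, T3: 190..283 — which tile the
291-day span exactly; boundary days belong to the window whose printed range
contains them (day 94 is T1). Per window the dam's stressor presence flags
(mastitis, lameness, antimicrobial, anti-inflammatory), mean THI$_{max}$ and
milk-quality bands are computed. Band edges are half-open $(a, b]$: a
printed ">0–3%" band accepts values above 0 up to and including 3, so bands
are exhaustive and disjoint, and a window with no recording is an explicit
"missing" level. BCS bands use the textual definition (normal = 1.5–3.25,
inclusive); locomotion is lame iff the window maximum score is ≥ 4. Window
membership of a milk recording uses its calendar date, not DIM.

Cow-level features add the mother's LRS centered on the dataset mean (a
proxy for genetic merit) and meteorological season of birth; farm-level
features add the mean 305-d yield of lactations starting in the 12 months
before the calf's birth and the farm's mean dam parity in the birth year.
Pregnancy number is collapsed to {2, 3, 4+}; first pregnancies are excluded
at pairing because the dam was not lactating, so production covariates
would be undefined.

## Record cleaning

The cow cascade removes, in order: identifiers seen on more than one farm;
cows not entering the herd on their birth date; cows with evidence of a
lactation before entry; births outside the study window; cows without a
calving; and ages at first calving outside the open interval (458, 1461) d —
the day equivalents of 15 months and 4.5 years, applied exclusively at both
bounds. Milk rules then drop records of unknown cows, exclude outright any
cow with milk before her first calving (she was not first-parity at entry),
bracket records into lactations half-open on the next calving with 0-based
DIM, and remove daily yields above 100 kg. Every step logs animal and
record counts, and the report is monotone by construction.

Free-text treatment records are matched to a product reference list by the
partial-ratio similarity: the shorter string (length $m$) is slid over every
length-$m$ substring of the longer, the best window's Levenshtein distance
$d$ gives $100(1 - d/m)$, case-folded and whitespace-trimmed. The acceptance
threshold defaults to 90/100 and is configurable, since the original
matching was verified manually; the matched table doubles as the audit
artifact. Product names containing configurable dry-cow keywords ("dry
cow", "DC") set a flag so dry-cow therapies can be included or excluded per
analysis. Farm-years enter the analysis only when at least one stressor
(mastitis, lameness, antimicrobial or anti-inflammatory — not vaccines) was
recorded.

## Mixed models

Daughter LRS $y_{ijk}$ for calf $i$ of dam $j$ on farm $k$ is modelled as
$y_{ijk} = \beta_0 + \beta' x + f_k + u_{jk} + e_{ijk}$ with independent
Gaussian random intercepts at farm and dam level (or dam-only for the
2-level variant), fitted by maximum likelihood so nested fixed structures
are comparable. Forward selection recomputes every remaining candidate's
joint Wald test against the grown model at each step (the standard forward
scheme) and enters the smallest $P < 0.05$; min/median/max summaries of one
milk variable form a subgroup of which at most one member may enter.
Polynomial terms up to degree 3 are then tested for selected continuous
predictors, and declared interactions enter only when significant *and*
AIC-improving. Ties are broken by declaration order and every decision is
traced. Wald tests on multi-level categorical terms are joint chi-square
quadratic forms across the term's coefficients; per-level Wald intervals are
still reported in the coefficient table. No multiple-testing correction is
applied.

Variance explained follows the marginal/conditional decomposition:
marginal $= \mathrm{var}(X\hat\beta)/(\mathrm{var}(X\hat\beta) + \sum
\hat\sigma^2_{re} + \hat\sigma^2_e)$, conditional replaces the numerator
with fixed plus non-residual components, so conditional ≥ marginal always.
Cross-validation leaves out one farm (or trial group) per fold, refits the
selected fixed structure, and predicts held-out rows from fixed effects only
— the random effect of an unseen group is its prior mean of zero.

## The synthetic herd generator

`sim_config()` defaults define the study conditions rather than a tuning
surface: 8 farms × 40 founder cows born 2006–2007, three pedigree
generations with retained-heifer probability 0.5 inside a 2006–2015 birth
window, calving intervals 400 ± 45 d, AFC 760 ± 60 d, MilkBot parameters
with farm- and cow-level spread around a 32-kg scale, monthly milk
recording, daily stressor hazards of 2–5 × 10⁻⁴ thinned by a farm-year
recording completeness of 0.85, and UK-like weather (13 ± 8 °C annual
sinusoid, dewpoint a strictly positive spread below the maximum, so
dewpoint ≤ T always holds).

The injected in-utero effect acts on a latent resilience scale:
latent = farm effect (SD 142) + dam effect (SD 81) + effect × (centered
window exposure) + residual (SD 477), the variance magnitudes matching the
random-effect structure the scoring model is meant to recover and the
default effect −5 points per THI$_{max}$ unit of mean trimester-3 exposure.
The latent value is deliberately *not* written to any output column as an
outcome; it is translated into survival (completed lactations, ~1 lactation
per 900 latent points), yield-scale deviation (+3% per 100 points) and
calving-interval deviation (−3 d per 100 points), so the signal reaches the
analysis only through the computed LRS. Truth tables record latent values,
true exposures, effect sizes and the pedigree for verification.

What the generator does not emulate: genetic transmission and sire effects,
disease dynamics, culling-policy changes over time, barn microclimate
(airflow, shade), or correlated measurement error in recording. Passing
tests therefore demonstrate that the pipeline recovers effects *of the kind
injected* under realistic noise — not that any particular real-world herd
would show them.

## Numerical and design choices

- Lactation bracketing is half-open $[c_j, c_{j+1})$; DIM is 0-based.
- DIM at the end of lactation $j$ is the next interval for non-final
  lactations and exit − last calving for the final one; a missing exit date
  falls back to the last milk-recording date + 1, flagged.
- Cow-lactations without a converged fit contribute neither to herd daily
  means nor to their own score (the cow's score is missing, counted).
- The mixed-model optimizer is lme4's default with ML; singular fits report
  the affected component as 0 and are flagged rather than discarded.
- Whether candidate P-values are recomputed at each step or screened
  marginally was an open choice; recompute-at-every-step is implemented.
- Problem sizes in the shipped tests and scripts (e.g. 8 × 40 cows for the
  workflow, 50 farms × 100 cows × 50 replicates for the recovery study,
  200 null simulations at n = 500) were chosen as the smallest designs at
  which the operating characteristics stabilise.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_farms = 4, cows_per_farm = 20, seed = 1)
res <- run_pipeline(cfg)
head(res$lrs[c("cow_id", "lrs", "lactation_bonus", "afc_component",
               "early_exit_penalty")])
res$selection$selected
res$r2
```

## Known limitations

- The LRS depends on herd averages, so scores are comparable within, not
  across, herds (or subherds in the research-herd variant).
- Exposure is station-level; the true microclimate an animal experienced is
  unobserved, adding classical measurement error that attenuates estimates.
- The fuzzy-matching threshold trades recall against precision and should
  be audited per dataset; the audit table exists for exactly that purpose.
- With desk-scale herds the THI contrasts carry modest power; the recovery
  study at 50 × 100 shows what sample size the design needs.
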