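---
title: "Estimating hidden-population sizes with the social-app multiplier method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hidden-population sizes with the social-app multiplier method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appmultiplier)
```

## The problem

Key populations in HIV surveillance — here, men who have sex with men
(MSM) — are hidden: there is no sampling frame, and membership is
stigmatised, so neither a census nor a household survey can count them.
The multiplier method estimates the population size from two
independent data sources: a **count** of population members enrolled in
some defining source (here, active users of a dating app in a province
over one month), and a representative **survey** of the population
measuring the **proportion** who are in that source. If $C$ app users
were counted and a fraction $\hat p$ of the population uses the app,

$$\hat N = \frac{C}{\hat p},$$

with a confidence interval obtained by dividing $C$ by the bounds of
the CI for $\hat p$. Provincial estimates are then converted to
age-weighted percentages of the adult male population and extrapolated
regionally to a national total.

Each stage of that pipeline is a module of this package, and every
stage can be validated against a synthetic population with known
ground truth.

## Counting app users (`dedup_count`, `capture_recapture_count`, `provider_count`)

Three interchangeable approaches produce the numerator:

1. **Deduplicated enumeration.** Daily sightings of profiles are
   filtered to profiles seen on at least `min_appearances` distinct
   days with at least two sightings `min_spacing_days` apart. The
   spacing rule removes short-term visitors. The field description of
   the spacing rule ("several days") is unquantified, so
   `min_spacing_days` is an explicit parameter (default 3 days) that an
   analyst must own rather than a hidden constant.
2. **Two-sample capture–recapture.** Profiles active at two time
   points are matched; Lincoln–Petersen $\hat N = n_1 n_2 / m$ or
   Chapman's bias-corrected $(n_1+1)(n_2+1)/(m+1) - 1$ estimates all
   active users. A normal-approximation CI from the estimator's
   standard variance is attached, floored at $\max(n_1, n_2)$.
3. **Provider aggregate.** A single unduplicated figure supplied by
   the app administrator.

Counts enter the multiplier as fixed constants: the provincial CI
arithmetic varies only the proportion, which matches how such studies
report their intervals. Fingerprint matching is exact string equality;
fuzzy profile matching is out of scope.

## The RDS survey and the two proportion estimators

Respondent-driven sampling (RDS) seeds a handful of community members
(6–8 per province), each of whom receives 3 coupons to recruit peers,
who recruit onward in turn. Because recruitment follows social ties,
high-degree members are oversampled; estimators reweight by the
self-reported network size (degree $d_i$).

**RDS-I (Salganik–Heckathorn).** With binary groups $A$ (app users)
and $B$, the recruitment transition proportions $S_{XY}$
(`transition_matrix()`) and harmonic mean degrees
$D_X = n_X / \sum_{i \in X} 1/d_i$ give the reciprocity-balance
estimate

$$\hat P_A = \frac{S_{BA} D_B}{S_{AB} D_A + S_{BA} D_B}.$$

The raw maximum-likelihood transition proportions are the default; a
reciprocity-symmetrised variant (`smoothed = TRUE`, replacing the
off-diagonal counts by their mean) is available because published
analyses do not always state which variant their software used — and
for that reason exact numerical replication of published provincial
proportions is not attempted here.

**Gile's SS (successive sampling).** RDS is modelled as sampling
without replacement with probability proportional to degree from a
finite population of assumed size $N$. Starting from weights
$\propto 1/d_i$, the algorithm alternates between (i) scaling the
weighted sample degree distribution up to a population of $N$ and
(ii) estimating each degree class's inclusion probability $\pi(d)$ by
Monte-Carlo simulation of the successive-sampling draw, iterating
until the estimated degree distribution stabilises; the estimate is
the $1/\pi(d_i)$-weighted sample proportion. Two numerical choices
matter:

* The simulation uses the exponential-race representation of
  weighted sampling without replacement for populations up to
  $2 \times 10^5$ units and an exact class-level sequential draw for
  larger $N$, so the $N \to \infty$ behaviour (convergence to the
  degree-weighted Hájek estimate) is reachable in seconds.
* The stopping tolerance on the degree distribution defaults to
  `5e-3` with 200 simulation replicates per iteration: the Monte-Carlo
  noise of the class proportions at that effort is about $2 \times
  10^{-3}$, so a much tighter tolerance cannot be met and would only
  burn iterations. A non-converged fit is returned with a flag, never
  silently.

$N$ is required input although the multiplier's purpose is to estimate
it — a circularity the source design leaves unstated. Both resolutions
are provided: pass an external `N`, or let `run_pipeline()` iterate
SS → multiplier → SS until the implied $N$ changes by less than 1%.

**Bootstrap CIs.** Both estimators use a chain-structured bootstrap:
each replicate regrows a pseudo-chain of the original length, starting
from the group of a uniformly drawn seed, stepping through the observed
transition matrix, and drawing degrees with replacement from the
group's empirical pool; the estimator is applied per replicate and the
CI is the percentile interval (default 1000 replicates). Replicates on
which the estimator is undefined are dropped; if more than 20% fail
the interval is flagged unreliable. Seeds contribute to the degree
pools but each replicate starts only one chain. Inside Gile's SS
replicates the simulation effort is reduced (25 replicates, 2
iterations) to keep the bootstrap tractable; the coverage experiment in
the test suite shows 95% intervals covering the true prevalence
with frequency ≈ 0.94 under random mixing.

## The diagnostic battery and estimator selection

* **Homophily** (`homophily()`): observed same-group recruiter–recruit
  pairs divided by the count expected if recruiters drew recruits at
  random from the realised recruit pool. 1 = random referral; > 1 =
  assortative. Published prose sometimes reads the statistic in the
  opposite direction; this package implements the standard convention
  and the selection rule uses the numeric threshold exactly as
  printed. Among candidate statistics (Heckathorn's group homophily
  vs a recruitment ratio) the recruitment-ratio form was chosen
  because it is computable from the recruitment pairs alone and has a
  permutation null of exactly 1.
* **Convergence** (`convergence_check()`): the estimator recomputed on
  every prefix of the sample in recruitment order must stay within
  ±2 percentage points (`tol = 0.02`, absolute; a relative mode
  exists because "within 2% of the sample proportion" is ambiguous)
  of the final estimate over the last quarter of the series
  (`window_frac = 0.25`; the window length is a package choice, the
  stability rule is standard). The cumulative RDS-I series is computed
  in $O(n)$ by accumulating transition counts and inverse-degree sums.
* **Bottleneck** (`bottleneck_series()`): the cumulative series
  restricted to each seed's subtree; the maximum gap between final
  per-seed estimates is reported, flagged above 0.10 by default since
  no numeric criterion is standard.
* **Sensitivity** (`sensitivity_check()`): a proportion outside
  [0.2, 0.8] (inclusive bounds) makes $C/\hat p$ hypersensitive to
  small errors in $\hat p$ and is screened out.

**Selection rule** (`select_estimator()`): RDS-I tends to
underestimate when sampling has not converged; the SS bootstrap tends
to underestimate when homophily is below 1 or seeds are biased. Across
provinces, count provinces with homophily < 1 and provinces that did
not converge; choose RDS-I exactly when the first count exceeds the
second, and Gile's SS otherwise (ties included — the tie-break is a
package decision and is noted in the rationale string).

`compare_groups()` reports the equal-variance two-sample *t* test
(pooled df $n_1+n_2-2$, matching the integer-like df in published
group comparisons) for continuous outcomes and Pearson's chi-square
without continuity correction for binary ones.

## Extrapolation

`weighted_msm_percentage()` allocates an 18–49 provincial estimate to
5-year age bands (15–19 through 45–49) proportionally to the app
users' age distribution. Because the survey enrols adults (18+) but
the reporting denominator is males 15–49, the 15–19 band share — which
can only contain 18–19-year-olds — is rescaled by $5/2$ under a
uniform-age-within-band assumption. This bridge is a modelling
assumption, not a measurement, so it is controlled by `bridge_15_17`
and recorded in every national report.

`extrapolate_national()` averages observed provincial percentages
within each geographic/socioeconomic region (population-weighted by
default; unweighted mean and median are available because the original
stratification detail is not public), applies the regional percentage
to the 15–49 male population of each unobserved province, and sums
observed, extrapolated and pilot estimates. The national CI applies
the identical procedure to the provincial CI bounds — a bound-wise,
conservative propagation that assumes nothing about independence
across provinces. Pilot provinces are listed in the configuration as
observed (so they are not extrapolated) and contribute their
previously published estimates.

## The synthetic-data generator

`generate_network()` builds a two-group degree-corrected mixing
network: degrees are zero-truncated negative binomial (mean
`degree_mean`, dispersion `degree_dispersion`), group A has exactly
`round(N * prevalence)` members, and edges are placed by
degree-weighted stub matching with the within-group edge categories
upweighted by `homophily_w` (1 = random mixing), duplicates and
self-loops dropped, and isolated nodes re-attached. `simulate_rds()`
walks the network with coupon-limited uniform recruitment among
unsampled neighbours (the standard RDS simulation assumption; nodes
with no eligible neighbours return coupons unused), reporting true
degrees by default with an optional multiplicative log-normal noise
hook, since real surveys rely on unvalidated self-reports.
`simulate_activity_log()` emits one row per (member, active day) with
group-specific daily login probabilities plus Poisson one-day visitor
profiles.

Default study conditions mirror the surveyed design: 6 seeds, 3
coupons, samples of 400 from populations of 10,000, mean degree 10
(the surveys' mean self-reported network size was 10.6 — a calibration
convenience, not an estimate, since MSM network topology in Vietnam is
unknown), app-use prevalence 0.35, 30-day logs with daily login
probability 0.3 for users, and 28% of non-recent users reporting
ever-use (the ratio implied by the published account/30-day columns).
All randomness flows from the single `rng_seed` through one generator;
a fixed seed reproduces network, sample and log byte for byte.

What the generator does **not** emulate: realistic geography,
age-structured mixing, app-account churn, degree misreporting by
default, or seed selection by convenience. Passing parameter-recovery
tests therefore demonstrates internal consistency of the estimators
under the stated network model, not robustness to the violations real
RDS data exhibit.

## Problem sizes used in validation

The shipped experiments use populations of 10,000 (recovery and
coverage), 30–50 simulated surveys per recovery experiment, 200
datasets × 500 bootstrap replicates for the coverage study, and 200
replicates for the capture–recapture accuracy study; these sizes give
Monte-Carlo error comfortably below the tolerances asserted while
keeping a full validation run in minutes on a single core.

## Known limitations

* Two-group traits only; multi-category estimators are out of scope.
* RDS-II / Volz–Heckathorn is not offered publicly (the degree-weighted
  Hájek form appears only as the large-$N$ limit in tests).
* The chain bootstrap conditions on the observed transition matrix;
  with very few cross-group recruitments its intervals are wide and
  may be flagged unreliable, mirroring provinces where the estimator
  fails outright.
* Published provincial CI totals differ by one unit from the column
  sums of the printed bounds (rounding in the source); the reporting
  table reproduces exact totals only for counts and point estimates.
* The age bridge and the regional averaging scheme are assumptions;
  both are configurable and flagged in output rather than silently
  applied.
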