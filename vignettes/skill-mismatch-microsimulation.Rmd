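---
title: "Projecting labour-market mismatch with skillsim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting labour-market mismatch with skillsim: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skillsim)
```

## Why microsimulation

Labour supply depends on the joint distribution of age, sex, education,
origin, duration of stay and participation; labour demand depends on
population size and the skill composition of jobs. Modelling their
interaction with aggregate multistate methods would require an impractically
large state space, so `skillsim` simulates individuals: every demographic,
educational and labour-market event is a Monte Carlo draw at the person
level, and aggregates (vacancies, mismatch, underutilization) are computed
by counting. One agent represents `scale_factor` persons; every reported
person count is an agent count times that factor, and all rates are
scale-invariant.

## The simulation loop

For each calendar year the engine applies, in order: aging (one-year step),
mortality, emigration, between-region migration, external immigration,
fertility, education revelation, labour-force participation, demand
projection, and occupation allocation. Events use the rates of the current
5-year period. The ordering within a year — deaths before exposure-based
events, occupation drawn last against that year's demand and labour force —
is a modelling convention; annual steps were chosen over 5-year steps to
avoid coarse age-group artifacts while still reporting on 5-year marks.
Rates stated per 5-year increment (the retraining scenario) are annualized
as `p1 = 1 - (1 - p5)^(1/5)`.

Reproducibility: a master seed spawns one L'Ecuyer-CMRG stream per module
(`rng_streams()`), so a run is a pure function of (bundle, scenario, seed)
and perturbing one module's draw count does not perturb the others. This is
what makes scenario contrasts at a fixed seed meaningful: the retraining
scenario, for example, consumes a dedicated stream for its post-draw
reassignment, leaving every other draw identical to the reference run.

## Demography

*Mortality.* Annual death probabilities by single age (0–100), sex,
education and period. The fixture uses a Gompertz–Makeham hazard
`h(x) = A + B e^{0.105x}` (plus a small infant excess), with the level `B`
found by a 1-D root search so that the medium-education life-table e0
matches the assumed path (female 83.5 → 91.2, male 77.6 → 85.6 between
2020–24 and 2055–59, linearly interpolated between anchors and held flat
beyond). Education enters as proportional hazards (low 1.25, high 0.82);
medium is the calibration reference. The age cap is 100: `q(100) = 1`, so
e0 is bounded by 100.5 under the mid-year death convention (`q ≡ 0`
elsewhere gives exactly cap + 0.5, and `q ≡ 1` gives 0.5).

*Fertility.* A gamma-shaped age profile over ages 15–49 (shape 6, rate 0.35;
mean age at birth ≈ 31) scaled so the medium-education schedule sums exactly
to the TFR path 1.51 / 1.58 / 1.64 (2020–24 / 2035–39 / 2055–59). Education
multipliers (low 1.12, high 0.92) are stylized; the published assumptions
state the aggregate path but not the education gradient, so the gradient's
magnitude is a documented choice. Sex ratio at birth is the conventional
105:100. Newborns record their mother's education, which feeds the
intergenerational term of the education model at age 15.

*Migration.* External inflows are scheduled in persons per year
(piecewise-constant per 5-year period, so the 2020–24 total equals the
assumed 15,272,419 exactly), split over two external origin groups: `ext_A`,
a smaller, higher-educated group with better labour-market outcomes, and
`ext_B`, the larger rest-of-world group. Arrivals draw age, sex and
education from schedule distributions, start with duration 0 and
`age_at_imm = age`. Emigration rates by origin class and broad age are
scaled so the expected base-year outflow matches the assumed 5-year volume.
Between-region rates converge linearly to a common target by 2050; movers
keep their birth region, are reclassified (`native` → `other_region`), and
restart their duration clock — a convention, since "duration of stay"
is residence in the current region.

## Education and participation

Final attainment is a cumulative logit over {low, medium, high}:
`P(level ≤ j) = logistic(t_j − lp)` with `lp` linear in birth cohort
(plateaued after cohort 2035 to avoid degenerate extrapolation), sex,
mother's education and region of birth. The two cut-points are solved by
root-finding so the region-and-sex mixture at the reference cohort (born
1988) reproduces the assumed 2020 shares at ages 30–34
(12.96 / 47.88 / 39.15); the cohort slope is the average logit displacement
implied by the assumed 2060 shares over 40 cohorts. The latent level is
drawn once at age 15 and *revealed* at 15 (low), 18 (medium) and 22 (high);
until revealed the individual is in school and outside the labour force.
This schedule is a design decision: the underlying behavioural assumption is
"highest level attained over the life course", which fixes the destination
but not the timing. Attainment is absorbing — only occupational skill, not
attainment, is moved by the retraining scenario. `mother_edu = "unknown"`
(base population and immigrants) maps to a neutral offset of zero.

Participation is logistic with a baseline per 5-year age group and offsets
for education, sex, origin group, recent arrival (duration < 5 years, the
"migrated within the last five years" convention) and childhood arrival
(age at immigration < 15, which largely offsets the origin penalty). The
age-group baselines are calibrated by root-finding against a 500,000-agent
synthetic calibration population so that expected participation per broad
age group matches 38.6 / 85.3 / 36.3 (ages 15–24 / 25–54 / 55–74) in the
base year. The in-school exclusion means the 15–24 rate is reached through
a higher rate among the out-of-school.

## The occupation module

The core of the package. Active individuals face a multinomial logit over
{unemployed, low-, medium-, high-skill job} with unemployment as the
reference category (a choice — the model statement leaves the reference
unnamed; all sign statements here are against unemployment). Covariates:
sex; education coded 0/1/2; their interaction; the 5-year age-group index
(1–12 for 15–19 … 70–74) and its square; immigrant-composite dummies
(origin group × recent/settled, childhood arrival, other modelled region)
with education and sex interactions; and two demand ratios — high-skill
demand over labour force, and combined low-plus-medium demand over labour
force, both computed within-year after the participation draw. Combining
low and medium demand into one predictor mirrors the estimation practice
that stabilizes the demand coefficients.

Fixture coefficients are synthetic values chosen to reproduce the documented
sign structure: strong education gradient into high-skill work and out of
unemployment; unemployment falling and high-skill work rising with age;
immigrant penalties largest for recent arrivals from the disadvantaged
origin group, narrowing with duration, negligible for childhood arrivals;
all demand coefficients positive (higher demand reduces unemployment) with
the largest loading on the matching skill group.

*Calibration.* Raw probabilities are rescaled per country and outcome,
`p'_k = λ_k p_k / Σ_j λ_j p_j`, with factors computed once in the base year
so the aggregated calibrated probabilities match the observed base-year
occupation distribution, then held constant. Aggregated over a
heterogeneous population this has no closed form, so the factors are found
by multiplicative iterative proportional updating
(`λ_k ← λ_k · target_k / model_k`, reference renormalized to 1, tolerance
1e-6 on the maximum share error, at most 500 iterations); a zero target
share floors its factor at 1e-9 with a warning. The procedure is idempotent
(recalibrating returns factors of 1) and its fixed point is verified against
a brute-force grid search in the tests.

*Allocation.* One uniform draw per individual against the cumulative
calibrated probabilities. Occupation is re-drawn each year — the allocation
is cross-sectional, with no persistence rule; scenario operators that move
workers (retraining) act after the draw. Demand is a covariate, not a hard
cap, so occupied jobs can exceed demand in principle and vacancies are
reported signed.

*Estimation.* `fit_multinomial_logit()` maximizes the multinomial
log-likelihood by Newton–Raphson with step-halving, using the analytic
gradient and block Hessian; convergence requires a gradient max-norm below
1e-8, standard errors come from the inverse observed information, and the
fit aborts with informative errors on rank-deficient designs (naming the
offending columns), missing outcome categories, and separation (estimates
diverging past ±30 on the logit scale). Recovery of known coefficients from
50,000 simulated records and agreement with an independent optimizer are
tested.

## Labour demand

Total demand is `population × r_c`, a fixed country ratio — demand follows
demographics only, with no macroeconomic feedback (a stated model
limitation). The fixture ratios (0.50 / 0.45 / 0.41) average to ≈ 0.46 jobs
per person, the level implied by ≈ 206.5 million jobs for ≈ 446.8 million
persons in the base year, and lie inside the observed 0.4–0.6 band;
an outlier ratio of 0.77 (a cross-border labour market) is available by
configuration. A multiplier path on the ratio is the single hook used by
both ±1-SD sensitivity runs and the automation scenario.

The skill split is a generalized-logit trend: `log(s_H/s_M)` and
`log(s_L/s_M)` each linear in year with additive region offsets, fitted by
least squares (the estimator behind "generalized logit regression" is not
pinned down in the source material; two independent log-ratio regressions
with renormalization is the implementation choice, exact for logit-linear
histories). Shares are clamped to [1e-6, 1−1e-6] before the transform. The
fixture history (2010–2019) is generated exactly on this family, anchored
so the 2020 split is ≈ 42/49/9 and the 2060 projection ≈ 55/36.5/8.5
(high/medium/low): with a positive high slope and a small positive low
slope, the projected high share is strictly increasing and the medium share
strictly decreasing through 2060.

## Scenarios

All operators start in 2025 and are inactive before. The seven built-ins:
inflow ×1.5; arrivals take the `ext_A` parameter blocks (implemented as
relabelling the arrival's origin group, which substitutes its education,
participation and occupation behaviour at once); education odds ×1.25 for
unrevealed cohorts born ≥ 1990 (both cut-points shifted by −log 1.25, i.e.
the odds of medium-and-above and of high both rise 25%); retraining moves
5% of medium-skill workers up and 5% of low-skill workers up per 5-year
increment (annualized, post-draw); participation of the 50+ replaced by a
stylized high-participation benchmark schedule (synthetic Swedish-level
magnitudes: 0.90 / 0.86 / 0.73 / 0.33 / 0.15 for 50–54 … 70–74); demand
multiplier falling linearly to 0.85 at 2060 ("gradual" is interpreted as
linear, configurable); and hiring odds ×1.25 for the job one skill level
above the education-matched one (low → M, medium → H; the high-educated
have no level above). The reference scenario is an empty operator list and
is bit-identical to running without a scenario layer.

## What the stylized fixture does and does not emulate

Three regions with high / medium / low attainment profiles stand in for 27
countries: enough to exercise every between-country mechanism
(origin-specific behaviour, between-region migration, region dummies in the
demand trend, per-country calibration) at desk scale. The generator's
aggregates match the headline assumptions by construction, and the full
pipeline reproduces the qualitative projection patterns — rising high-skill
demand share, sharply rising low- and medium-skill vacancy rates, declining
underutilization among the high-educated, automation collapsing the vacancy
rate while raising underutilization.

What passing tests on the fixture do **not** show: country-level numeric
projections (the fixture's coefficients are synthetic, not estimated from
survey microdata); realistic within-country heterogeneity (base-population
education is independent of origin, a documented simplification); wage,
sectoral or fiscal detail; probabilistic uncertainty (runs are
deterministic scenario projections, seed-to-seed Monte Carlo variation is
not a forecast interval). The projected 2060 aggregate demand exceeds the
published EU27 figure because the stylized age structure yields a roughly
stable population rather than a mildly declining one; all mismatch
statistics are driven by composition, not by this level.

## Numerical choices and degenerate inputs

Softmax predictors are max-shifted before exponentiation; probability rows
sum to 1 within 1e-12 at every stage. Agent counts from person-denominated
inflows are stochastically rounded (floor plus Bernoulli remainder), so
expectations are preserved exactly. Ties in multinomial draws are
measure-zero; draws use a single uniform against cumulative probabilities,
which couples scenario contrasts monotonically. Empty populations pass
through every verb; an empty base spec yields an empty state with the year
set. Missing schedule cells abort with the offending cell named.
Underutilization divides by the active labour force (the denominator is a
documented choice; the alternative — all workers — is a one-line change in
`underutilization()`).

## Problem sizes

The default bundle simulates 200,000 agents (≈ 2,234 persons per agent);
the acceptance suite runs the fixture-calibration checks at that size and
the scenario battery as five full 2020–2060 runs, and the estimation
recovery checks use 50,000 simulated records; unit tests use 20,000–50,000
agents. These sizes were chosen so binomial sampling error is well below
each tested tolerance (3 standard errors of the relevant proportion) while
a full battery stays comfortably interactive.
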