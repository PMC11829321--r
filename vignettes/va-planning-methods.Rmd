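---
title: "Methods: least-cost planning of vitamin A intervention packages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: least-cost planning of vitamin A intervention packages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaoptim)
```

## The planning problem

Dietary vitamin A inadequacy among children 6--59 months of age is assessed
by comparing the vitamin A *density* of the household diet (µg retinol
activity equivalents per 1000 kcal) with each child's *critical density* —
the child's age- and sex-specific estimated average requirement (EAR)
divided by their energy requirement, per 1000 kcal. A child whose household
diet density falls strictly below their critical density is counted
inadequate; a tie counts as adequate (the strict inequality must be fixed
one way or the other for reproducibility, and we fix it so that a diet
exactly meeting the requirement is adequate).

A planner can intervene through two channels:

* **Large-scale food fortification (LSFF)** — national programs fortifying
  edible oil (an existing program at 39% compliance and 85% of the
  17.5 mg/kg standard, or an improved variant at 75% compliance and the
  full standard) or bouillon cubes (hypothetical programs at 48 or
  96 mg/kg, i.e. 15% or 30% of the adult Codex NRV in a 2.5 g serving, at
  75% compliance). Fortification adds
  `vehicle_g_day × level_mg_kg × compliance × relative_level`
  µg RAE/day to the household diet (mg/kg read as µg/g); energy is
  unchanged, so density rises.
* **Vitamin A supplementation (VAS)** — macro-regionally targetable
  campaign/clinic delivery, modelled as a daily-equivalent intake of
  167 µg RAE for covered children. Rather than assuming a child's share of
  household energy, we subtract the 167 µg from the child's EAR before
  forming the critical density, which is algebraically equivalent at the
  requirement scale and needs no extra assumption.

The *effective coverage* of a set of programs is the drop in the
child-level inadequacy prevalence relative to the no-program baseline,
multiplied by the projected child population. Coverage is **not additive**
across programs — two programs that each leave a household just below a
child's threshold can jointly push it across — so every package is
evaluated jointly against the survey. Costs, in contrast, are assumed
linearly additive across programs.

A *program package* combines at most one oil program, at most one cube
program, and any subset of the five macro-regional VAS programs; selecting
all five regions is the national VAS option. With 2 oils, 2 cubes and 5
regions this gives `3 × 3 × 2^5 − 1 = 287` non-empty packages (8 of them
national-only). For each of 40 coverage targets — starting at ~1% of the
discounted pool of inadequate children and rising in ~2.5
percentage-point steps — the planner picks the package that meets the
target at minimum discounted cost:

$$\min_{N,S} \sum_{t=1}^{10} \frac{C_t(N,S)}{(1+r)^{t-1}}
\quad\text{s.t.}\quad
\sum_{t=1}^{10} \frac{EF_t(N,S)}{(1+r)^{t}} \ge \overline{EF},$$

with $r = 0.03$. We implement the discount exponents exactly as written
(costs $t-1$, benefits $t$); the asymmetry may well be unintentional, so
`discounted_sum()` and `va_optimize()` expose the offsets and both can be
set to $t-1$. None of the package's checks depends on the distinction.

Because the feasible set is finite and small, the solver is **exhaustive
enumeration**, not a linear-programming relaxation: non-additive benefits
make each package an indivisible alternative, and 287 packages × 10 years
is trivial compute. Ties are broken deterministically: lower cost, then
higher coverage, then fewer member programs, then canonical package id.

## Timing of benefits and costs

New programs need setting up before benefits flow. Bouillon programs pay
start-up costs in years 1--2 and deliver benefits (completely and
immediately) from year 3; the improved oil program pays start-up in year 1
and delivers from year 2; the current oil program and VAS programs are
already in place and deliver from year 1. In a package's pre-benefit
years, its not-yet-active programs are simply dropped from the scenario
for that year — a cube-only package has zero effective coverage in years
1--2 even though it is paying start-up costs there.

Cost profiles are split by stakeholder (government, industry, premix) and
phase. Start-up components are spread uniformly across the start-up years
(phase lengths are known; the within-phase schedule is not, and a uniform
spread is the neutral choice). Operational components run from the year
after start-up through year 10 and, where population-scaled, grow with the
child-population index — national for LSFF programs, regional for VAS.
Three perspectives are supported: government only; government + industry
(the default, net of premix, since these are the stakeholders who decide
on and implement programs); and all three.

## Demography

Each macro-region has child-population anchors for year 1 (2023) and for
the year after the horizon ends (2033). Within the horizon we interpolate
with a constant annual growth rate $g = (\text{final}/\text{base})^{1/10}
- 1$ (about 1.62%/yr nationally). Only the endpoints are published, so the
interpolation rule is a modelling choice; geometric growth matches how
population prospects are usually projected, and a linear option is
provided (`projection = "linear"`). Child counts are kept as real numbers
internally and rounded only when reported, to avoid drift in discounted
sums.

The discounted pool of inadequate children — the denominator for all
"percent of inadequate children" figures and the base of the target grid —
is the 10-year benefit-convention discounted sum of
(baseline prevalence × child population) across regions.

## The synthetic survey generator

The generator emulates the statistical structure the adequacy model
assumes, so the full pipeline is testable without any microdata download:

* **Household energy intake**: lognormal, median 9000 kcal/day (a
  several-person household), log-sd 0.35.
* **Household vitamin A density**: lognormal with log-sd 0.6 — positive
  and right-skewed, as apparent-intake densities are. The log-mean is
  calibrated *per region* by bisection so that the simulated child-level
  baseline inadequacy matches the region's published prevalence (88--99%).
  Calibration happens after all random draws, so it is deterministic given
  the seed, and the achievable accuracy is floored at the sample's
  one-child prevalence granularity $1/n_\text{children}$; at the default
  2000 households the contractual ±1 percentage point always binds.
* **Vehicle consumption**: a household consumes bouillon with a
  region-specific probability (0.70--0.95, highest in the North, lowest in
  the West, ~82% on average) and oil with probability 0.55; consuming
  households draw gamma amounts with means 8 g/day (cube) and 25 g/day
  (oil). Consumption is independent of density — no correlation is
  published, and a correlated extension would slot in here.
* **Children**: 0--3 per household (probabilities 0.25/0.40/0.25/0.10),
  ages uniform over 6--59 months, sex balanced. Children inherit the
  household diet density; there is no intra-household allocation model,
  matching how household-survey-based adequacy assessment works.
* **Requirements**: a configurable table; the default uses IOM-style
  vitamin A EARs (190/210/275 µg RAE by age band) over FAO-style energy
  requirements by age band and sex, giving critical densities of roughly
  185--290 µg RAE/1000 kcal. The published analysis cites but does not
  print its requirement tables, so these are free inputs.
* **VAS coverage and costs**: per-region coverage rates (0.70--0.85) and
  all cost magnitudes are synthetic placeholders at nationally plausible
  scale — the underlying cost interviews are not published. The
  *structural* facts are contractual and tested: bouillon start-up spans
  exactly 2 years, improved oil 1, VAS none; profiles split by
  stakeholder; VAS programs are per-child-cost-driven and each costs more
  over 10 years than any LSFF program.

What passing tests therefore show is that the *machinery* — calibration,
adequacy accounting, discounting, optimization, robustness — is correct
under realistic structure; they do not validate the magnitudes of the
published country results, which depend on unpublished microdata.

VAS receipt is randomly assigned child-by-child at the region's coverage
rate, once per fit with a fixed seed, and reused across scenarios and
years (per-year re-randomization is not stated anywhere, and a single
assignment keeps scenario comparisons noise-free).

## Robustness to uncertainty

Central benefit and cost estimates are perturbed with proportional shocks:
for each program, one benefit deviate and one cost deviate drawn from
$N(0, 0.1)$ per simulation (480 simulations by default), constant across
the program's 10 years and shared by every package containing the program
within that simulation. "Central estimate plus deviation" is read
multiplicatively because the deviations are described as percentage
changes (68% of draws within ±10%, a further 27% between 10% and 20%).
Multipliers are floored at zero — a more-than-10-sigma event — and floors
are logged.

Costs re-aggregate exactly (additive). Package-level benefits are
non-additive, so a perturbed package's coverage is its central coverage
scaled by the coverage-weighted mean of its members' benefit multipliers,
each member weighted by its share of the package's standalone-coverage
sum; single-program packages reduce to exact scaling. The alternative —
re-running the adequacy engine with shocked fortification levels — is
possible but re-simulates diets the published procedure holds fixed.

Each simulation re-solves all 40 targets; results are summarized by
dividing the realized achieved-coverage values (pooled over simulations
and targets) into 20 quantile-spaced bins and ranking packages by how
often they are optimal within each bin, reporting the top two. Binning on
achieved coverage (rather than on the nominal target grid) reflects that
the feasible coverage range is only realized through the simulations.

## Numerical choices and degenerate inputs

* Prevalence ties (density exactly equal to critical density) count as
  adequate, everywhere.
* Bisection for density calibration runs on the bracket
  [log 1, log 20000] µg RAE/1000 kcal for at most 100 iterations and
  fails loudly, naming the region, if the tolerance (floored at $1/n$)
  cannot be met.
* Zero-coverage packages report an `NA` cost per child rather than
  dividing by zero; infeasible targets are flagged, never silently
  dropped.
* Empty package sets, empty regions, non-positive populations, negative
  costs, and duplicate oil/cube programs in one scenario are rejected
  with validation errors.
* The Monte Carlo solver sorts packages once per simulation under the
  deterministic tie-break and scans the running coverage maximum; it is
  tested to agree exactly with the reference per-target solver.

## Problem sizes

The shipped defaults run the complete analysis — a 2000-household survey,
287 packages, 40 targets, 480 simulations — in a few seconds on one CPU;
unit tests use an 80-household fixture. These sizes are the package's
defaults for routine use; all of them scale up linearly through
`synthetic_config()` and the function arguments.

## Known limitations

* Benefit perturbation uses the weighted-multiplier aggregation above; it
  is exact for single-program packages and an approximation for joint
  packages.
* The generator draws vehicle consumption independently of diet density
  and income; real surveys show socioeconomic gradients in both.
* No biological absorption or serum-retinol modelling: inadequacy is
  purely dietary, as in the source analysis.
* Survey weights are carried through all prevalence computations but the
  generator emits unit weights; complex design effects are out of scope.
* The dual problem (maximize coverage under a budget) is not implemented.

## A worked run

```{r, eval = FALSE}
bundle <- generate_bundle(synthetic_config(seed = 1))
fit <- va_optimize(bundle$survey, bundle$regions, seed = 1)
summary(fit)
sims <- simulate(fit, nsim = 480, seed = 1)
summary(sims)
plot(fit)
```
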