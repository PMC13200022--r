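---
title: "Evaluating and optimising programme meals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and optimising programme meals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

snpmeals evaluates the meals that India's Integrated Child Development
Services Supplementary Nutrition Programme (ICDS-SNP) serves to children
aged 36–72 months at Anganwadi centres, and searches for low-cost menu
improvements by linear programming. This vignette describes the model
behind each stage, the tunable parameters and their defaults, the design
choices that were genuinely open, and what the synthetic data generator
does and does not emulate.

```{r setup}
library(snpmeals)
```

## From menus to nutrient provision

The unit of observation is one anganwadi-day: the raw grams of each
ingredient served per child on one operational day of a repeating menu
cycle (typically 6–15 days). Given a food composition table of densities
per 100 g raw food over a fixed ten-nutrient panel (energy, protein, fat,
calcium, iron, zinc, folate, vitamins A, B6 and B12), provision is the
linear form

$$T_k = \sum_f \frac{g_f \, n_{f,k}}{100},$$

with $g_f$ the raw grams of food $f$ and $n_{f,k}$ its density of
nutrient $k$. Quantities are raw-ingredient grams throughout; cooked-yield
and retention modelling is out of scope. Only programme-funded ingredients
count towards provision — foods supplied through other safety-net schemes
are recorded but excluded (and the exclusions are counted in the run
manifest). A day on which nothing programme-funded was served is kept as an
all-zero provision, because such days are part of the day-to-day
variability the simulation is meant to capture.

Composition entries from different databases are made comparable by
moisture adjustment: every density is scaled by
$(100 - m_\text{target}) / (100 - m_\text{source})$, which preserves
nutrient per unit dry matter exactly and is invertible.

Fortified staples are handled as overlays on the composition table. The
shipped specification mirrors common programme practice: rice carrying
4.25 mg iron, 12.5 µg folic acid and 0.125 µg vitamin B12 per 100 g, and
edible oil carrying 750 µg vitamin A per litre. Whether declared levels
are *additions* over the unfortified base or *total* contents is genuinely
ambiguous in programme documents; the package defaults to the increment
reading (matching the "added amount" convention of Indian fortification
standards) and offers `fortification_mode = "total"`, implemented as a
raise-to-level (`pmax`) so that fortification can never lower a density in
either mode. Per-litre oil levels convert to a per-100 g basis through a
configurable mass density, default 0.92 g/ml — a typical value for edible
vegetable oils; the source document gives only µg per litre, so the
density is a package choice.

## State-level simulation

State-wise means $m$ and variances $v$ of each nutrient are computed over
anganwadi-day observations pooled across the state's surveyed centres —
the finest unit the data model supports; the sample variance uses the
unbiased $n-1$ denominator, with $v = 0$ for single-observation states
rather than an error. A lognormal distribution is then fitted by moment
matching,

$$\sigma^2 = \ln\!\left(1 + v/m^2\right),\qquad
  \mu = \ln m - \sigma^2/2,$$

so the fitted distribution's analytic mean and variance equal $(m, v)$
exactly. The lognormal is a natural model for provision: positive,
right-skewed, and degenerating cleanly to a point mass when $v = 0$.
Moment matching (not maximum likelihood) is used because the procedure is
defined in terms of the state mean and variance. Nutrients never provided
($m = 0$) are reported as zero provision and not simulated.

Each state–nutrient distribution is then sampled 1000 times (the default
`n_draws`), and the median and interquartile range of the draws summarise
daily provision. Quartiles use the linear-interpolation convention
(R's type 7), fixed explicitly because quartile definitions differ across
software. A seed is mandatory: the full summary is a pure function of
(data, seed, n_draws), and rows are sorted by state and nutrient before
sampling so the result does not depend on input order.

## Adequacy rules

Two standards versions are built in:

| parameter | snp2012 | snp2023 |
|---|---|---|
| energy target | 500 kcal | 400 kcal |
| protein | ≥ 12 g (floor) | 15–20 g (15 g floor operative) |
| fat | 25–35 % of energy | 15–20 g absolute |

Micronutrients are scored against `meal_fraction` (default one-third) of
the age-specific Estimated Average Requirement for 3–6 year olds. EAR
values are user-supplied configuration; the shipped
`default_ear_synthetic()` table is a labelled synthetic example with
plausible magnitudes, not an authoritative requirements table.

Two distinct layers are kept apart deliberately:

* **Met / not met** uses a 10 % flexibility margin (`tolerance`): energy
  is met at ≥ 90 % of target, protein at ≥ 90 % of its floor,
  micronutrients at ≥ 90 % of one-third EAR, and the fat band is widened
  by 10 %.
* **Traffic lights** use the reporting bands: green ≥ 90 %,
  yellow 80 – < 90 %, red < 80 %, with provision more than 10 % above the
  recommendation also red for energy and fat (the excess rule). Band
  edges are half-open — exactly 90 is green, exactly 80 is yellow —
  because "80–90 %" is ambiguous at its endpoints.

Protein is evaluated twice: crude, and corrected by a digestibility
factor (default 0.8, appropriate for predominantly cereal-based diets);
with `digestibility = 1` the two evaluations coincide exactly. For fat the
10 % allowance widens **both** edges of the band by default
(22.5–38.5 % of energy); whether the allowance was meant for the lower
edge only is not decidable from the available description, so
`fat_allowance = "lower_only"` provides the alternative reading. The
protein upper figure (15 g in 2012, 20 g in 2023) is reported but not
used for failure: evaluation is against the lower bound. Adequacy is
computed on the simulated median by default (`evaluate_state()`), with
`evaluate_provision()` available to score any provision vector directly.

## The menu linear programme

The optimiser solves the classic diet problem: choose grams
$x_f \ge 0$ of state-listed candidate foods minimising
$\sum_f p_f x_f$ (mean vendor prices, ₹/g) subject to

* energy inside a 0.9–1.1 × target band — the upper bound keeps the
  solver from buying adequacy through excess energy, which matters in a
  population facing a dual burden of under- and overnutrition;
* protein ≥ the programme floor, with digestibility-weighted densities by
  default;
* fat per the standards rule — for the ratio rule the band becomes the
  two linear constraints $9 f - 0.25 E \ge 0$ and $9 f - 0.35 E \le 0$;
* each micronutrient ≥ one-third EAR (floors only);
* per-food portion caps, and a total raw-gram cap (default 350 g/day)
  standing in for young children's limited gastric capacity — there is no
  numeric guidance for this value, so it is configurable.

Variables are continuous grams; no integer portions. The budget is *not*
a hard constraint in the primary objective: the per-child allocation
(default ₹8/day) is a post-hoc reference, and `cost_gap()` reports
`max(0, cost − allocation)` — matching the observation that optimised
improvements typically exceed the current allocation. A secondary
goal-programming objective (`objective = "min_shortfall"`) inverts the
question: minimise the total relative shortfall below the nutrient floors
subject to cost ≤ allocation, the "best feasible menu under budget".

In *additions* mode an existing menu day is held fixed; its nutrient
contribution is credited against every constraint, decision variables are
increments, the volume cap applies to base plus additions, and the
reported cost includes the base menu (so the cost gap is the gap of the
improved day as a whole).

Solving uses the two-phase tableau simplex method. Every returned optimum
is re-checked against all constraints independently of the solver's own
report at tolerance 1e-6, and status (`optimal` / `infeasible` /
`not_converged`) is reported faithfully. For validation, a brute-force
grid oracle (`lp_brute_force()`, at most four foods) exhaustively searches
gram multiples of a step; on floor-only problems, rounding the LP optimum
up coordinate-wise stays feasible, which bounds the oracle–LP cost
difference by (sum of per-gram prices) × step — the bound the test suite
asserts over random problems.

## The synthetic generator

No survey data ship with the package, so `gen_dataset()` fabricates
everything the pipeline needs. Densities and prices are drawn uniformly
within per-food-group plausibility ranges shipped as a labelled synthetic
fixture (`food_group_ranges_synthetic.csv`) — field-realistic magnitudes,
deliberately not a redistribution of any published composition table.
Menus come in two profiles:

* `cereal_heavy` emulates the observed pattern: a morning snack and a
  rice- or wheat-dominated hot cooked meal, with day-to-day gram jitter,
  occasional non-programme milk (flagged and excluded), and a cereal
  energy share falling inside the 38–77 % band by construction.
* `adequate` solves a small full-mode LP against the 2012 standards over
  a nutrient-dense candidate list and serves the optimal grams
  identically every day (a 0.5 % uplift keeps binding floors strictly met
  after rounding). This guarantees the test suite a feasible, all-green
  fixture without hand-tuned numbers.

A fraction of states (default half) uses the fortified rice staple; oil
fortification applies programme-wide. What the generator does **not**
emulate: any specific real state's menu, seasonal and district variation,
correlated day-to-day menus (draws are independent), within- vs
between-centre variance structure, and cooked-portion measurement error.
Green test results on synthetic states therefore demonstrate that the
*machinery* is correct, not that any real state's meals are adequate.

## Numerical choices and degenerate inputs

* Energy from fat uses the 9 kcal/g Atwater factor; the fat-to-energy
  ratio is undefined (an error) on zero-energy days, and a fully zero
  provision is scored red across the board rather than erroring.
* `fit_lognormal()` refuses $m \le 0$; callers report "not provided"
  instead (zero quantiles, $\sigma = 0$).
* Simplex right-hand sides must be non-negative, so constraint rows with
  negative right-hand sides are sign-flipped during assembly; in additions
  mode a base already above an upper bound is detected as infeasible.
* Grid-oracle ties are broken by the first minimal grid point in
  column-major order; LP determinism follows from the deterministic
  tableau pivoting.
* Problem sizes used in the shipped tests and examples — 1–3 synthetic
  states, 200–1000 draws, $10^4$-observation recovery checks, 50 random
  oracle comparisons — were chosen to exercise every code path while
  keeping the default suite quick on a laptop.

## Worked example

```{r example, eval = FALSE}
ds <- gen_dataset(synthetic_config(seed = 42, n_states = 3),
                  include_adequate = TRUE)
std <- snp_standards("snp2012", ear_per_day = default_ear_synthetic())

provisions <- compute_provisions(ds$menu, ds$foods, ds$fortification)
summary <- summarize_states(provisions) |>
  simulate_states(n_draws = 1000, seed = 7)
adequacy <- evaluate_state(summary, std)
autoplot(adequacy)

foods_fortified <- apply_fortification(ds$foods, ds$fortification)
result <- lp_problem(foods_fortified, ds$prices, std) |> lp_solve()
glance(result)
```

## Known limitations

Bioavailability is modelled only through the single protein digestibility
scalar; there are no recipe yield or retention factors; per-meal (morning
snack vs hot cooked meal) standards are not evaluated — the meal label is
kept in the data model but all computations pool the day's foods; and the
probability-of-adequacy across the full simulated distribution (the EAR
cut-point prevalence) is out of scope — adequacy is a statement about the
simulated median.
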