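# snpmeals

Evaluate the meals that India's Integrated Child Development Services
Supplementary Nutrition Programme (ICDS-SNP) serves to preschool children
(36–72 months) at Anganwadi centres, and search for low-cost menu
improvements by linear programming.

The package is for nutrition researchers and programme analysts who have
(or can emulate) three inputs: a food composition table (nutrient densities
per 100 g raw food), state menu cycles (raw ingredient grams per child per
day), and local vendor prices. From these it:

1. **computes per-child daily provision** of a fixed ten-nutrient panel
   (energy, protein, fat, calcium, iron, zinc, folate, vitamins A, B6,
   B12), with moisture adjustment and fortified-staple overlays
   (e.g. rice with 4.25 mg iron / 12.5 µg folate / 0.125 µg B12 per 100 g;
   oil with 750 µg vitamin A per litre);
2. **simulates state provision distributions**: per-state means and
   variances (m, v) are moment-matched to a lognormal,
   σ² = ln(1 + v/m²), µ = ln m − σ²/2, and 1000 draws give the median and
   IQR of daily provision;
3. **scores adequacy** against the 2012 standards (500 kcal, 12 g
   protein, 25–35 % fat-to-energy) and the revised 2023 standards
   (400 kcal, 15–20 g protein, 15–20 g fat), plus one-third of the
   age-specific EAR for micronutrients, with a 10 % flexibility margin, a
   0.8 protein-digestibility correction, and green/yellow/red
   traffic-light bands (≥90 / 80–90 / <80 %, with an excess rule above
   110 % for energy and fat);
4. **optimises menus** as a diet problem: minimise Σ p_f x_f subject to
   nutrient floors and bands, portion and meal-volume caps, either from
   scratch or as additions to an existing menu, and reports the gap
   between the optimal cost and the ₹8 per-child daily allocation. A
   budget-capped shortfall-minimising mode answers the inverse question.

A seeded synthetic-data generator fabricates realistic multi-state
datasets (cereal-dominant cycles, 6–15-day menus, fortified staples,
vendor quotes), so the whole pipeline runs and is tested without any
survey data. See the vignette (`vignettes/snp-meal-evaluation.Rmd`) for
the model details and design choices.

## Worked example

```r
library(snpmeals)

ds  <- gen_dataset(synthetic_config(seed = 42, n_states = 3),
                   include_adequate = TRUE)
std <- snp_standards("snp2012", ear_per_day = default_ear_synthetic())

provisions <- compute_provisions(ds$menu, ds$foods, ds$fortification)
summary    <- summarize_states(provisions) |>
  simulate_states(n_draws = 1000, seed = 7)
adequacy   <- evaluate_state(summary, std)
glance(adequacy)
#> # A tibble: 1 × 5
#>   standard_version n_states n_rules pct_met pct_green
#>   <chr>               <int>   <int>   <dbl>     <dbl>
#> 1 snp2012                 3      33    60.6      60.6
```

33 rules were scored (3 states × 11 rules: energy, crude and digestible
protein, fat, seven micronutrients); 60.6 % were met. Inspecting one
cereal-heavy state shows the familiar pattern — iron, zinc and folate
comfortably met, energy just below target, and calcium, vitamin A and
vitamin B12 far short:

```r
dplyr::filter(adequacy, state_id == "ST01")
#>    nutrient       provision requirement pct_of_requirement met   status
#>  1 energy_kcal      426.         500                  85.1 FALSE yellow
#>  2 protein_g         10.5         12                  87.8 FALSE yellow
#>  3 protein_g          8.43        12                  70.2 FALSE red
#>  4 fat_g             22.5         25                  90.0 TRUE  green
#>  5 calcium_mg        54.7        147.                 37.3 FALSE red
#>  6 iron_mg            7.55         2.9               260.  TRUE  green
#>  7 zinc_mg            2.73         1.63              167.  TRUE  green
#>  8 folate_ug         61.2         36.7               167.  TRUE  green
#>  9 vitamin_a_ug      14.8         96.7                15.3 FALSE red
#> 10 vitamin_b6_mg      0.397        0.25              159.  TRUE  green
#> 11 vitamin_b12_ug     0.0908       0.333              27.2 FALSE red
```

Optimising a day's menu over the full (fortified) food list at current
prices:

```r
foods_fortified <- apply_fortification(ds$foods, ds$fortification)
lp_problem(foods_fortified, ds$prices, std) |> lp_solve()
#> <snp_lp_result> status: optimal (min_cost, simplex)
#>   grams: rice=39.4, ragi=60.5, egg=27.6, spinach=45.8, oil=5.5
#>   cost: Rs 10.00 (allocation Rs 8.00, gap Rs 2.00)
```

The cheapest day meeting every 2012 target costs ₹10.00 — ₹2.00 above the
₹8 allocation — and leans on egg and green leafy vegetables, the same
nutrient-dense additions that drive costs in practice.

`run_pipeline()` chains all stages from input files to a report bundle
(`provisions.csv`, `state_summary.csv`, `adequacy_<version>.csv`,
`foodgroup_shares.csv`, `lp_result.json`, `manifest.json`), and
`inst/scripts/snp-eval.R` wraps `synth` and `run` for shell use.

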