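# anemiasom

Self-organizing-map subtyping of nutritional and socio-economic profiles
for anemia risk in prospective cohorts.

## What this is for

Anemia — hemoglobin < 130 g/L (men) / < 120 g/L (women) — is tied to diet
and socio-economic position, but not uniformly: rice- vs wheat-based
diets, income, fibre and iron intake interact differently across
population segments. For epidemiologists working with cohort tables
(demographics, anthropometry, biochemistry, 3-day food-group intakes,
derived nutrients, follow-up anemia status), this package provides the
full multivariable subtyping pipeline:

* **Derived variables** — anemia, low iron intake (< 20 mg/day for women
  18–49, < 12 mg/day otherwise), obesity (BMI > 28), hypertension,
  diabetes, IDF-2005 metabolic syndrome, income encoding
  (1000/3500/5000 Yuan/person), and per-sex height calibration of
  intakes.
* **Matching** — sex-stratified greedy age matching of controls to cases
  (maximal pool with Welch p > 0.05), and greedy nearest-neighbour
  matching of an independent training set on network-module principal
  component scores.
* **Correlation-network modules** — sex-weighted Spearman network
  (`w_f·ρ_f + w_m·ρ_m`), maximum-spanning-forest pruning on |ρ|, greedy
  modularity modules, per-module PC1/PC2 scores.
* **SOM subtyping** — within-sex rank normalization to [0, 1], batch
  Kohonen training (Gaussian neighborhood, radius 4 → 1, 8 × 6 lattice),
  best-matching-unit evaluation, map colorings, K = 4 contiguous
  subgroups (seeded k-means on the codebook, or a manual region table),
  and percentile-bootstrap subgroup summaries with the
  "evaluation-set mean outside CI95" flag.
* **Univariate machinery** — age residualization, sex-stratified Welch /
  logistic tests, Fisher combination (−2Σlog p ~ χ²₂ₖ),
  Benjamini–Hochberg FDR, number-weighted descriptives, adjusted
  logistic models with separation detection.
* **Fortification scenarios** — added iron = soy sauce / 1.12 g/mL ×
  level (mg/mL); change in low-iron prevalence per subgroup.
* **Synthetic cohorts** — a seeded generator over four published
  archetype profiles (High Fibre, Low Vegetable, Low Fibre, High Rice;
  subgroup incidences 10/25/10/27%) with ground-truth labels and
  realistic loss to follow-up, so every stage is testable without the
  original (undeposited) data.

## Worked example

```r
library(anemiasom)

cfg <- generator_config(n_participants = 2500, seed = 1)
sc  <- generate_cohort(cfg)                  # archetype mixture + baseline anemia
sc  <- apply_loss_to_followup(sc, cfg)       # younger / more male / higher-iron lost
sc  <- simulate_incident_anemia(sc, cfg)     # 5-year incidence per archetype
round(100 * mean(sc$cohort$anemia_baseline), 1)
#> [1] 30.7                                   # baseline prevalence, %

res <- subtype_pipeline(sc$cohort, n_boot = 2000, seed = 1)
res$model
#> som_model: 8x6 grid, 11 variables, 20 epochs
#>   quantization error: 0.7194 -> 0.6791

round(res$incidence, 2)                      # incident anemia per subgroup
#>    I   II  III   IV
#> 0.13 0.17 0.21 0.09

subset(res$summary, trait == "fibre")[, c("subgroup", "n", "mean",
                                          "ci_low", "ci_high", "outside_flag")]
#>    subgroup   n  mean ci_low ci_high outside_flag
#> 11        I 233  6.58   6.10    7.12         TRUE
#> 27       II 132 11.75  10.47   13.27        FALSE
#> 43      III 252  8.95   8.12    9.74         TRUE
#> 59       IV 123 25.74  23.33   28.01         TRUE

fort <- scenario_low_iron_delta(sc$cohort[match(res$eval_ids, sc$cohort$id), ],
                                res$membership, fortification_scenario(4))
fort
#>   subgroup   n baseline_prevalence scenario_prevalence delta_pp
#> 1  overall 740              17.027               1.216  -15.811
#> 2        I 233              25.751               1.717  -24.034
#> 3       II 132              24.242               3.030  -21.212
#> 4      III 252              13.095               0.397  -12.698
#> 5       IV 123               0.813               0.000   -0.813
```

The summary rows read like the published subgroup tables: subgroup mean,
bootstrap CI95, and a flag when the whole-evaluation-set mean falls
outside the CI. The fortification table says a +4 mg/mL iron-fortified
soy sauce scheme would, at the theoretical maximum, cut low-iron-intake
prevalence by 15.8 percentage points overall in this synthetic
evaluation set, with almost no headroom in the high-rice subgroup —
the qualitative pattern the method is designed to expose. (Note the
learned subgroup labels I–IV are map regions, not the generator's
archetype names; agreement with the ground truth is measured by adjusted
Rand index, here 0.46.)

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "anemiasom", package = "anemiasom"))')
$CLI generate --seed 1 --out cohort.csv --truth truth.csv
$CLI derive   --in cohort.csv --out derived.csv
$CLI match    --in cohort.csv --out match.json
$CLI network  --in cohort.csv --out-prefix net
$CLI som      --in cohort.csv --out-prefix som
$CLI fortify  --in cohort.csv --level 4 --out scenario.csv
```

Configs for `generate` are JSON (YAML accepted when the `yaml` package is
installed).
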