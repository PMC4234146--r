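# wamindex

Household socioeconomic status (SES) measurement for multicountry child
health studies.

Epidemiological studies that pool households across diverse low- and
middle-income settings need an SES measure that is comparable across sites:
income is noisy and hard to collect, country-specific wealth quintiles do
not pool, and asset lists must be selected and weighted somehow. `wamindex`
implements four household wealth measures on a common footing and a simple
composite SES index, together with the validation machinery to compare them
against child height-for-age Z-scores (HAZ):

* **maternal education** — completed years of schooling (the baseline);
* **tetrachoric PCA** — the first principal component of the tetrachoric
  correlation matrix of screened binary asset indicators, scored per
  household with prevalence-standardized loadings;
* **adapted MPI** — a household-level Multidimensional Poverty Index with
  equally weighted education / health / living-standard dimensions,
  reported as wealth (1 − deprivation);
* **RF asset score** — the unweighted count of eight priority assets
  selected by conditional permutation importance in a regression forest
  with HAZ as the outcome;
* **WAMI** — the composite index:

  WAMI = (W + A + M + I) / 32,

  where W = 4·(improved water) + 4·(improved sanitation) ∈ {0, 4, 8},
  A = count of the 8 selected assets (0–8), M = maternal education years
  (0–16) / 2, and I = USD income octile score (1–8 against the fixed
  cutoffs 26 / 47 / 72 / 106 / 135 / 200 / 293, or empirical octiles).

Supporting machinery: Cronbach-alpha indicator screening, two-step
maximum-likelihood tetrachoric estimation with PSD repair, conditional
(within-strata) permutation importance, leave-one-out and stratified k-fold
cross-validated prediction error, adjusted R² with site indicators, scaled
"25%-increase" effect sizes, income construct-validity checks, and a seeded
synthetic multicountry cohort generator so that every stage is testable
without external data.

## Worked example

Read a survey through a codebook (column mapping, indicator coding,
exchange rates), score the WAMI index, and estimate the scaled effect size:

```r
library(wamindex)

csv <- system.file("extdata", "example_survey.csv", package = "wamindex")
cb  <- system.file("extdata", "example_codebook.yaml", package = "wamindex")
cohort <- read_cohort(csv, cb)
#> <wami_cohort> 6 households, 2 sites, 4 asset indicators

w <- wami(cohort, assets = c("radio", "tv", "fridge", "mobile_phone"))
w[, c("household_id", "water_san_score", "asset_score",
      "education_score", "income_score", "wami")]
#>   household_id water_san_score asset_score education_score income_score
#> 1         B001               0           1             1.5            4
#> 2         B002               4           3             4.0            6
#> 3         B003               8           4             6.0            8
#> 4         B004               0           0             0.0            3
#> 5         B005               8           2             3.0            6
#> 6         B006               8           4             5.0            8
#>       wami
#> 1 0.203125
#> 2 0.531250
#> 3 0.812500
#> 4 0.093750
#> 5 0.593750
#> 6 0.781250

es <- effect_size_25(cohort, w$wami, rescale = FALSE)
sprintf("25%%-increase effect: %.3f (95%% CI %.3f to %.3f)",
        es$estimate, es$ci[1], es$ci[2])
#> "25%-increase effect: 0.680 (95% CI -0.252 to 1.612)"
```

Household B004 (no improved water or sanitation, no assets, no schooling,
~60 USD/month) scores near the composite floor of 1/32; B003 reaches
0.81 with full water/sanitation points and the top income octile. The
effect size says a 25% increase in WAMI is associated with a 0.68 SD
higher HAZ in this toy cohort — with six households the CI is wide and
crosses zero, as it should.

The full pipeline on a synthetic 8-site cohort:

```r
g <- generate_cohort(generator_config(seed = 11))
cmp <- compare_methods(g$cohort, cv = "kfold", k = 10, seed = 11)
cat(format_comparison_md(cmp), sep = "\n")
```

which prints the method-comparison table (cross-validated MSE, adjusted R²,
effect size per 25% of each measure's range, variable counts) for the five
measures.

A command-line pipeline over the same functions ships in
`inst/cli/wami.R` (subcommands `simulate`, `select`, `score`, `validate`,
`report`).

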