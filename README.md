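# imodkit

Tools for decomposing a bacterial gene-expression compendium into
**i-modulons** — independently modulated gene sets — and for working with
their condition-specific activities.

A compendium of log-TPM profiles, centered on a reference condition, is
modeled as

```
X = S A + E
```

with **S** (genes × components) holding sparse per-gene coefficients of
statistically independent signals and **A** (components × samples) their
activities. imodkit implements the full workflow around this factorization:

- **Preprocessing** — log-TPM from counts and gene lengths, QC filters
  (genes ≥ 100 nt, ≥ 10 fragments per million in at least one sample,
  replicate R² ≥ 0.9), centering on reference samples.
- **Robust ICA** — FastICA (logcosh contrast, symmetric updates, Rcpp core)
  restarted from many random initializations, pooled components clustered
  with DBSCAN under the sign-invariant correlation distance
  `d = 1 − |ρ|`, sign-aligned cluster centroids, and a cross-repetition
  robustness filter that keeps only components reproduced in every
  repetition at `d < 0.1`.
- **Thresholding** — iterative removal of the largest-|coefficient| genes
  until the D'Agostino K² normality statistic of the remainder drops below a
  cutoff (default 550; calibrate against a regulon table with
  `scan_cutoff()` or cross-validate with `cross_validated_cutoff()`).
- **Regulon enrichment** — two-sided Fisher's exact tests against single and
  combined regulons (intersections `+`, unions `/`, up to three regulators),
  BH-FDR control, precision/recall/F1, and i-modulon categorization.
- **Activities** — log-normal replicate-noise model, differential-activity
  testing (significant when `|ΔA| > 5` and FDR < 0.01), exact i-modulon
  subtraction to correct strain differences, and least-squares projection of
  new profiles onto a fixed basis (`A' = pinv(S) X'`).
- **Synthetic fixtures** — a generator planting sparse modules with known
  activities and a matching toy regulon table (with decoys), so the whole
  pipeline is testable without external data.

Fitted objects are plain S3 with broom-style `tidy()`/`glance()` and
ggplot2 `autoplot()` methods; result tables are tibbles.

## Worked example

```r
library(imodkit)

fx   <- generate_compendium(seed = 1)         # 4000 genes x 60 samples, 10 modules
comp <- center_to_reference(fx$compendium)
dec  <- robust_components(comp, n_restarts = 12, n_repetitions = 3, seed = 8)
dec
#> <imod_decomposition> 11 robust components over 4000 genes x 60 samples
#>   12 restarts x 3 repetitions

iset <- compute_imodulons(dec, cutoff = 550) |>
  enrich_imodulons(fx$regulon_table) |>
  categorize_imodulons()

glance(iset)
#> # A tibble: 1 x 4
#>   n_imodulons n_memberships cutoff n_regulatory
#>         <int>         <int>  <dbl>        <int>
#> 1          10           216    550           10

top_enrichment(iset)[, c("imodulon", "regulator_set", "p_value", "precision", "recall")]
#> # A tibble: 10 x 5
#>    imodulon regulator_set  p_value precision recall
#>    <chr>    <chr>            <dbl>     <dbl>  <dbl>
#>  1 IC01     Reg02         1.70e-40     0.882      1
#>  2 IC02     Reg08         1.87e-56     0.917      1
#>  3 IC03     Reg03         3.55e-64     0.897      1
#>  # ... one row per i-modulon, each linked to its true regulator
```

The eleventh robust component never crosses the significance threshold (it is
a reproducible direction of the noise realization, not a planted module), so
ten i-modulons remain; each recovers one planted module and is linked to its
true regulator with precision around 0.9 — the planted regulons cover 90% of
each module's members — and recall 1. The activities in `dec$A` are ~0 at the
two reference samples and track the planted condition blocks elsewhere;
differential activity between two conditions is tested with
`fit_replicate_noise()` + `test_differential_activity()`.

A thin command-line wrapper over the same functions is installed at
`inst/exec/imodkit` (subcommands `simulate`, `preprocess`, `decompose`,
`threshold`, `enrich`, `diffact`, `project`, `run`), and `run_pipeline()`
chains all stages from a YAML config with a manifest recording parameters,
seed, and input checksums.

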