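# mutpanel

Somatic mutations accumulate in normal epithelium long before a tumor is
diagnosed, and in the bladder they concentrate in the same short genomic
regions that are recurrently mutated in non-muscle-invasive (NMIBC) and
muscle-invasive (MIBC) bladder cancer. `mutpanel` is an R package for
turning that observation into a measurement pipeline:

1. **Discover** — place fixed-width (default 100 bp) mutation-capture
   windows over a tumor SNV catalog by greedy maximal capture (each window
   is anchored at a mutated position; every record is captured exactly
   once), rank them by capture count, and keep the top fraction
   (default 10%) as a candidate panel.
2. **Refine** — build the samples × windows burden matrix, gate on a
   one-way ANOVA across windows, and keep as **hotspots** the windows that
   beat more than half of the lower-ranked windows in all-pairs
   Tukey–Kramer HSD comparisons (adjusted *p* < α and larger mean).
3. **Compare** — per-sample-normalized window frequencies, Pearson
   correlation of hotspot burden between cohorts, Wilcoxon rank-sum /
   signed-rank tests, fold changes of mean burden, and equal-sized
   cold-spot control panels tiled from the least mutated footprint.
4. **Classify** — per-sample hotspot burden + personal risk factors (age,
   sex, smoking) into logistic-regression, neural-network and
   random-forest classifiers with a stratified 70/30 split, a rank-based
   ROC/AUC routine, and permutation variable importance on held-out data.
5. **Simulate** — a synthetic cohort generator (exon footprint, planted
   Dirichlet-weighted hotspot windows, negative-binomial per-sample
   burdens, risk-correlated covariates) with full ground truth, so every
   stage is validated by parameter recovery rather than by fiat.

The intended users are groups designing targeted sequencing panels for
field-cancerization burden measurement, and anyone who needs a
reproducible, tested reference implementation of the
window–ANOVA–Tukey hotspot selection procedure.

## Worked example

```r
library(mutpanel)

cfg <- sim_config(seed = 7)
fp  <- generate_footprint(cfg)                       # 60 exons, 12 kb
hs  <- plant_hotspots(cfg, fp, seed = cfg$seed + 1L) # 10 planted hotspots
coh <- generate_cohort(cfg, fp, hs, "tumor", 200, seed = cfg$seed + 2L)
coh$catalog
#> mutation_catalog 'tumor': 6038 SNV records, 200 samples

ranked <- rank_windows(place_windows(coh$catalog, fp, width = 100))
panel  <- top_fraction_panel(ranked, q = 0.10, name = "top10")
hot    <- refine_panel(coh$catalog, panel)
hot
#> window_panel 'top10_hotspots': 10 windows, total width 1000 bp
head(attr(hot, "decisions"), 4)
#>          window_id rank  mean frac_lower_ranked_beaten is_hotspot
#> 1   sim1:5050-5149    1 1.275                    0.750       TRUE
#> 2 sim4:19252-19351    2 1.190                    0.800       TRUE
#> 3 sim1:13599-13698    3 1.025                    0.643       TRUE
#> 4 sim2:19902-20001    4 0.965                    0.538       TRUE
```

The 17-window top-10% panel refines to exactly the 10 planted hotspots:
each hotspot window captures ~0.7–1.3 mutations per sample against a
background of ~0.2, and each beats the majority of the windows ranked
below it at Tukey-adjusted *p* < 0.05.

Burden in the hotspot panel versus an equal-sized cold-spot panel on the
same 200 samples (paired signed-rank):

```r
cold   <- coldspot_panel(ranked, nrow(hot$windows), fp,
                         catalog = coh$catalog, avoid = hot)
m_hot  <- per_sample_window_counts(coh$catalog, hot)
m_cold <- per_sample_window_counts(coh$catalog, cold,
                                   sample_ids = m_hot$sample_ids)
wilcoxon_compare(rowSums(m_hot$counts), rowSums(m_cold$counts), paired = TRUE)
#> [1] 8.812529e-34
```

Risk classification on a simulated normal-urothelium study (483 low-risk,
233 high-risk; high-risk samples carry 3× the hotspot weight, are 10 years
older on average and smoke more):

```r
st    <- generate_risk_study(risk_config(seed = 1))
feats <- assemble_features(st$catalog, list(mibc = st$panel), st$clinical,
                           "mibc+risk")
sp <- split_train_test(feats, 0.7, seed = 1)
rf <- fit_and_score(sp$train, sp$test, "random_forest", seed = 1)
rf
#> model_report: random_forest, test AUC = 0.9224
round(variable_importance(rf, sp$test, seed = 1), 4)
#>                 age     smoking_current hotspot_burden_mibc
#>              0.2045              0.0672              0.0408
#>      smoking_former            sex_male     smoking_missing
#>              0.0113              0.0024              0.0000
```

The random forest separates high- from low-risk samples with test AUC
0.92; permuting age costs the most AUC (0.20), with smoking and hotspot
burden next — age is the dominant risk signal in these conditions, and
hotspot burden adds on top of the personal risk factors.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mutpanel.R` (subcommands `simulate`, `discover`, `refine`,
`correlate`, `classify`).

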