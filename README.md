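# microvar

Temporal variability of longitudinal microbiomes, per patient and per
body site.

## The problem

Patients hospitalized for intensive chemotherapy are sampled repeatedly
(oral swabs, stool) over several weeks. Their microbial communities can
stay steady or swing violently as antibiotics and mucosal injury let
pathogens bloom. `microvar` condenses each patient's longitudinal series
at each body site into a single instability statistic — the
**coefficient of variation**

> CV = s / x̄ (sample standard deviation over the mean)

of (i) the per-sample α-diversity series (Shannon H = −Σ pᵢ ln pᵢ,
Gini–Simpson 1 − Σ pᵢ², bias-corrected Chao-1) and (ii) the set of
within-patient UniFrac distances (unweighted, and weighted-normalized
d = Σ l_b |p_a(b) − p_b(b)| / Σ l_b (p_a(b) + p_b(b)) on a rooted
phylogeny). Per site, the cohort is split at CV quartiles into
**stable / average / variable** patients. Around that core sit the
association screens: genus abundance vs. CV (Pearson + Benjamini–Hochberg),
genus abundance across stability categories (Kruskal–Wallis + BH), CV by
clinical outcome (Welch t, Mann–Whitney U), and a multivariable OLS of
each CV measure on clinical covariates (age, antibiotic exposures,
chemotherapy regimen).

Because cohorts like this are rarely shareable, the package ships a
seeded synthetic-cohort generator (`generate_cohort()`) that emulates the
study design — 59 patients, two sites, 6–9 samples each over ~4 weeks,
mean depth 28,622 reads — with planted per-patient volatility,
pathogen-bloom dynamics, antibiotic coupling and infection outcomes, so
every stage of the pipeline is testable against known ground truth.

## Worked example

```r
library(microvar)

co <- generate_cohort(cohort_config(n_patients = 30, depth = 2000, seed = 1))
alpha    <- alpha_table(co$table)
dm_wu    <- beta_matrix(co$table, co$tree, "weighted_normalized")
dm_uu    <- beta_matrix(co$table, co$tree, "unweighted")
profiles <- build_profiles(alpha, list(uu = dm_uu, wu = dm_wu), co$meta)

head(as.data.frame(profiles), 3)
#>   patient_id  site n_samples cv_shannon  cv_simpson   cv_chao1     cv_uu     cv_wu
#> 1       P001  oral         9 0.01991537 0.005090036 0.07996413 0.3126768 0.2756335
#> 2       P001 stool         6 0.01136957 0.001935834 0.12958182 0.1731637 0.1590960
#> 3       P002  oral         7 0.01006626 0.002172512 0.21717422 0.2837306 0.1941661

cross_site_correlation(profiles, "cv_shannon")
#> $r
#> [1] 0.4288836
#> $p
#> [1] 0.01803719
#> $n
#> [1] 30
```

`P001` and `P002` were planted stable (Shannon CVs near 0.01–0.02; the
cohort's volatile patients sit an order of magnitude higher), and across
the 30 patients the oral and stool CVs are moderately correlated
(r = 0.43, p = 0.018) — the shared patient-level volatility factor the
generator plants and the statistic is designed to expose.

```r
genus_rel <- relative_abundance(aggregate_genus(co$table))
res <- genus_cv_correlation(genus_rel, profiles, co$meta, "cv_wu", "stool")
head(res[c("feature", "statistic", "p_adj")], 3)
#>                           feature statistic        p_adj
#> Staphylococcus     Staphylococcus 0.4776154 2.318049e-13
#> Stenotrophomonas Stenotrophomonas 0.4556463 1.626706e-12
#> Enterococcus         Enterococcus 0.2980109 1.288668e-05
tail(res[c("feature", "statistic", "p_adj")], 2)
#>                               feature  statistic        p_adj
#> Pseudobutyrivibrio Pseudobutyrivibrio -0.3838331 6.364133e-09
#> Subdoligranulum       Subdoligranulum -0.4650903 6.762697e-13
```

Pathogen genera rank at the top (positive correlation with
community-structure instability, the Fig.-2-style row ordering); planted
commensal stabilizers (*Pseudobutyrivibrio*, *Subdoligranulum*) come out
at the bottom with negative correlations. The stable/average/variable
classification and the covariate regression:

```r
cats <- categorize(profiles, "cv_wu")
table(cats$site, cats$category)
#>         average stable variable
#>   oral       14      8        8
#>   stool      14      8        8

fit <- multivariable_ols(profiles, co$meta, "cv_shannon", "oral")
fit[fit$term == "days_all_abx", c("estimate", "p")]
#>     estimate           p
#> 6 0.06173038 0.001174689
```

Days on all antibiotics significantly predicts *oral* Shannon-CV (the
planted site-specific exposure effect); the same row in the stool
regression is null.

End to end, writing alpha/beta tables, profiles, categories, all
association TSVs and a JSON summary stamped with the config hash:

```r
run_pipeline(run_config(out_dir = "run1",
                        simulate = list(n_patients = 30, depth = 2000),
                        seed = 1))
```

or from the shell (script installed under `exec/`):

```sh
microvar simulate --seed 17 --out sim/
microvar run --config run.json
```

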