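# dietspec

Quantifying intrapopulation feeding diversity — how much individual
predators differ in what they eat — from DNA-metabarcoding diet profiles of
scat. The package was built around a large Salish Sea harbor seal
(*Phoca vitulina*) scat study design: prey read counts per scat, replicated
ZFX/ZFY qPCR sexing of the depositor, and repeated cross-sectional sampling
across haul-out sites, months and years. It is aimed at quantitative
ecologists working with compositional diet data from any scat- or
gut-content metabarcoding design.

## The metric and the model

Each scat *i* yields a diet proportion vector *p<sub>ij</sub>* (reads for
prey *j* / total reads). Scats are binned into Location × Sex × Year × Month
groups, and each sample is scored with the **proportional similarity
index**

> PSi = 1 − 0.5 Σ<sub>j</sub> | p<sub>ij</sub> − q<sub>j</sub> |

against its group's population diet *q* (the unweighted mean of member
diets). PSi = 1 is a perfect generalist; the attainable minimum in an
N-member group is 1/N (the *theoretical minimum*), reached by a sole
specialist on a resource nobody else touches. Groups smaller than 5 samples
are dropped to limit the 1/N bias; a Spearman diagnostic quantifies the
residual association between group size and mean PSi.

Downstream, logit-transformed PSi is modelled with linear mixed models
(REML) over the fixed effects Sex, Month and their interaction, with random
intercepts for Sample Size, Location and Year; models are ranked by AIC and
Akaike weights, with marginal/conditional r² from variance components.
Spearman correlations (Bonferroni-corrected) link specialization to
prey-order proportions and benthic diet fractions. A Dirichlet-multinomial
study simulator with a single specialization knob (the concentration *c*)
generates complete synthetic studies with known truth.

## Worked example

```r
library(dietspec)
library(dplyr)

tpl <- tidyr::expand_grid(location = c("Estuary A", "Reef B"),
                          sex = c("female", "male"),
                          year = c(2012, 2013), month = c(5, 7, 9)) |>
  mutate(n = 12)
study <- simulate_study(simulation_config(seed = 42, template = tpl))
res <- run_pipeline(study, bootstrap_R = 10000, seed = 42)
cat(res$log, sep = "\n")
#> dietspec 1.0.0 pipeline run
#> seed = 42, min_group_size = 5, bootstrap_R = 10000
#> sexing: 384 records, 281 sexed (73.2%), 102 excluded (no ZFX), 1 excluded (ZFY only)
#> grouping: 281 sexed samples in 24 groups
#> psi: 0 boundary PSi value(s) clamped before logit
#> filter: 24 of 24 groups retained (N >= 5); 281 samples retained
#> mean PSi = 0.445 (95% CI half-width 0.013, R = 10000)
#> models: best by AIC is 'Sex*Month' (wi = 0.643)
```

The sexing line mirrors the qPCR decision rules: 73.2% of simulated scats
were sexed (the generator's default extraction-failure and dropout rates
emulate the ~75% success of the motivating study). The mean PSi of 0.445
with a Monte Carlo 95% CI half-width of 0.013 says the average sample
shares about 45% overlap with its group diet — substantial but far from
generalist. The model comparison:

```r
select(res$model_comparison, -fit)
#> # A tibble: 4 × 6
#>   predictors  r2_fixed    r2   aic delta_aic       wi
#> 1 Sex*Month     0.186  0.379  387.      0    0.643
#> 2 Sex           0.0533 0.161  388.      1.55 0.297
#> 3 Sex + Month   0.0987 0.184  391.      4.75 0.0597
#> 4 Month         0.0165 0.146  401.     14.0  0.000579
```

recovers the generator's built-in sex difference (females are simulated
with a lower concentration, i.e. more specialised): every sex-containing
model outranks the month-only model, and the interaction model carries the
largest Akaike weight. `res$correlations$all` holds the per-order Spearman
table (negative rho = associated with specialization) and `res$benthic`
the benthic-fraction correlation.

The packaged study tables are available directly:

```r
hs_group_summary()     # 111 groups: N, 1/N, mean PSi, Shannon, retention
hs_sexing_counts()     # sexed-scat counts by site, year, month (total 1,145)
hs_model_comparison()  # the published four-model AIC table
reproduce_reference_targets()  # recompute + compare the headline statistics
```

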