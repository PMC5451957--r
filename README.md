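# pestmix

Joint-exposure analysis of residential proximity to agricultural pesticide
use, for environmental-epidemiology settings where many correlated
pesticides are applied near subjects' homes and single-pollutant
regressions cannot disentangle them.

The package covers the whole workflow:

1. **Exposure assessment** — convert use-report records (section, date,
   active ingredient, kg) plus residence and pregnancy windows into
   per-subject pregnancy-average use estimates, using exact 1-km-buffer
   area weighting of one-square-mile sections, a 75-day / two-trimester
   sufficiency rule, a median-and-contrast inclusion filter, and quartile
   discretization into exposure profiles.
2. **Bayesian profile regression** — an outcome-supervised
   Dirichlet-process mixture over the categorical profiles
   \(x_i = (x_{i1},\dots,x_{iP})\), fit by a blocked Gibbs sampler on a
   truncated stick-breaking representation, with a Gaussian outcome
   sub-model \(y_i \mid z_i = c \sim N(\theta_c + W_i\beta, \sigma^2)\),
   continuous variable-selection weights, posterior co-clustering, a
   least-squares "best" partition, and cluster-level adjusted-outcome
   posteriors against a low-exposure reference cluster.
3. **Characterization** — quartile heat-map labels per cluster and
   pesticide, cumulative-use ranking, and a second-stage OLS when the
   outcome is excluded from clustering.
4. **Kernel machine regression** — \(Y = h(z) + W\beta + \varepsilon\)
   with \(h\) marginalized into a Gaussian term with kernel
   \(K_{ij} = \exp(-\sum_p r_p (z_{ip}-z_{jp})^2)\) and hierarchical
   (grouped) variable selection, reporting group and conditional posterior
   inclusion probabilities per chemical class.
5. **Spatial statistics** — global and local Moran's I with permutation
   inference and Gaussian kernel-density surfaces of cluster residences.
6. **Synthetic scenarios** — a use-report generator with planted cluster
   structure, correlated zero-inflated log-normal amounts, and a
   cluster-structured outcome, so everything above is testable with known
   ground truth.

Everything is seeded end to end: one master seed reproduces every artifact
byte for byte.

## Worked example

Fit the profile-regression model on a synthetic preset that plants three
clusters with outcome effects (0, −6.9, −6.4) on the FSIQ scale behind ten
confounders:

```r
library(pestmix)

dat <- preset_fsiq_recovery(n = 300, seed = 1)
confounders <- dat$outcome_table[, -(1:2)]
fit <- bpr_fit(dat$profiles, dat$outcome_table$fsiq, confounders,
               config = bpr_config(n_burnin = 2000, n_sweeps = 20000,
                                   n_keep = 1000, seed = 2))
best   <- best_partition(fit)
ref    <- select_reference_cluster(best, dat$profiles)
report <- cluster_outcome_posteriors(fit, best, ref)
report
#> Cluster-level adjusted outcome posteriors (reference cluster: 1 )
#>  cluster   n             adjusted        difference deficit_probability
#>        1  99 102.3 (100.8, 103.9)               Ref                  NA
#>        2  97    95.5 (93.8, 97.2) -6.8 (-8.1, -5.6)               1.000
#>        3 100    96.3 (94.8, 97.8) -6.0 (-7.2, -4.8)               1.000
#>        4   1   96.9 (94.1, 106.3)  -5.4 (-7.8, 3.9)               0.925
#>        5   1   98.4 (89.4, 104.2) -3.9 (-13.1, 1.7)               0.689
#>        6   1  102.9 (96.4, 110.1)   0.5 (-5.8, 8.0)               0.293
#>        7   1   97.9 (92.3, 105.7) -4.4 (-10.3, 3.5)               0.859

compare_partitions(best, dat$ground_truth$true_cluster)
#> Partition comparison over 300 subjects (ARI = 0.960)
```

Reading the output: the sampler recovers the three planted clusters (plus
four transient singletons), selects the planted low-use cluster as the
reference, and estimates the two planted deficits at −6.8 (−8.1, −5.6) and
−6.0 (−7.2, −4.8) with deficit probabilities of 1.00 — the posterior
probability that the cluster's adjusted expected outcome lies below the
reference cluster's.  `autoplot(report)` draws the posterior CDFs per
cluster; `tidy(fit)` and `glance(fit)` give broom-style summaries.

The full pipeline (simulate → exposure → clustering with and without
outcome feedback → characterization → kernel model → spatial statistics →
report) runs from one call:

```r
run_pipeline(pipeline_config(n_subjects = 120, seed = 11), outdir = "run1")
pipeline_report("run1")
```

## Documentation

`vignettes/methods.Rmd` documents the models and their assumptions, every
prior and tunable parameter with its default, what the synthetic-data
generator does and does not emulate, and the numerical design choices
(log-space stick-breaking, truncation diagnostics, kernel exponent
tracking, percentile and tie conventions).
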