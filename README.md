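# connstates

Multimodal brain-connectivity analysis for cohorts split into abdominal and
non-abdominal obesity groups, and for linking connectivity to
eating-disorder behaviour. The package builds weighted graphs from three
measurement arms —

* **structural**: directed fiber-probability matrices from probabilistic
  tractography, summarised by degree centrality (in-degree + out-degree);
* **static functional**: Pearson correlation of node time series, mapped to
  an unsigned weighted network by soft thresholding
  `w = ((r + 1) / 2)^beta` (beta = 6), Fisher r-to-z transformed, and
  summarised by degree centrality (column sums);
* **dynamic functional**: tapered sliding-window covariances, inverted
  under an L1 penalty (graphical lasso,
  `log det(theta) - tr(S theta) - lambda ||theta||_1`), scaled to partial
  correlations, clustered into recurring brain states by K-means (state
  count chosen by per-subject silhouette voting), with per-state degree
  centrality and betweenness-based hub identification (normalised BC > 1.5)

— and compares them between groups with label-permutation tests under
Benjamini–Hochberg FDR, then regresses the four EDE-Q subscales (restraint,
eating, shape, weight concern) on the identified centralities with age as a
covariate, single-modality or combined.

A synthetic-cohort generator plants known brain states, group effects and
behaviour coefficients, so every stage of the chain is testable against
ground truth without neuroimaging data. Subjects are assigned to groups by
the waist–hip ratio rule (males > 0.9, females > 0.85 ⇒ abdominal obesity).

## Worked example

Generate a cohort with two planted states and a group effect on nodes 1–2,
then run the static arm and its group test:

```r
library(connstates)
coh <- generate_cohort(cohort_config(n_per_group = 10, p = 8, t = 400,
                                     k_states = 2, dwell_mean = 40,
                                     precision_sparsity = 0.15,
                                     group_effect_nodes = 1:2, seed = 42))
dc_static <- t(sapply(coh$ts, function(ts) static_dc(ts)$value))
perm <- permutation_test_dc(dc_static, coh$subjects$group,
                            n_perm = 2000, seed = 1)
tidy(perm)
#> # A tibble: 8 × 5
#>   node  observed_diff        p        q significant
#>   <chr>         <dbl>    <dbl>    <dbl> <lgl>
#> 1 V1          0.235   0.000500 0.001000 TRUE
#> 2 V2          0.215   0.000500 0.001000 TRUE
#> 3 V3          0.224   0.000500 0.001000 TRUE
#> 4 V4          0.00651 0.759    0.759    FALSE
#> 5 V5          0.0231  0.200    0.321    FALSE
#> 6 V6          0.234   0.000500 0.001000 TRUE
#> 7 V7         -0.0189  0.245    0.327    FALSE
#> 8 V8         -0.0137  0.444    0.507    FALSE
```

The planted effect sits on nodes 1–2; nodes 3 and 6 are their planted edge
partners, so their centrality shifts too — effects propagate along edges.
The dynamic arm recovers the planted state count and occupancies:

```r
dyn <- dynamic_states(coh$ts, cfg = window_config(16, 10, 3), lambda = 0.05,
                      k_range = 2:5, seed = 1)
tidy(dyn$group_states)
#> # A tibble: 2 × 3
#>   state occupancy n_windows
#>   <int>     <dbl>     <int>
#> 1     1     0.687       536
#> 2     2     0.313       244
```

And the behaviour regression links shape-concern scores to static DC with
age adjusted:

```r
fit <- fit_edeq_regression(coh$subjects$edeq_s, dc_static[, 1],
                           coh$subjects$age)
tidy(fit)
#> # A tibble: 3 × 5
#>   term        estimate std_error statistic    p_value
#>   <chr>          <dbl>     <dbl>     <dbl>      <dbl>
#> 1 (Intercept)  0.0705    0.490       0.144 0.887
#> 2 dc           6.18      0.973       6.35  0.00000724
#> 3 age          0.00706   0.00953     0.741 0.469
```

The slope is significant (the generator plants a DC→EDE-Q coefficient) and
the model explains R² = 0.72 at n = 20. `run_pipeline()` executes the whole
chain on a cohort laid out on disk (TSV in, TSV + JSON manifest out);
`write_cohort()` produces that layout from a generated cohort.

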