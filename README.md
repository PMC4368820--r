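# hta: heterogeneity-aware differential expression testing and method reliability benchmarking

Two-cohort expression contrasts are usually tested per feature with a
t-test or with the hybrid "p < 0.05 and |log2 FC| > 1" recipe. Both
mishandle **molecular heterogeneity**: in cohorts of genetically
different samples (patients above all), disease subtypes make the
member genes of the affected pathways genuinely differential in only
part of the cohort. The resulting spread is biology, not noise — but a
per-feature variance estimate mistakes it for error and deprioritizes
exactly the disease-relevant genes, while fold-change cutoffs discard
coordinated low-magnitude signals. This package is for transcriptomics
analysts and method developers who need (a) a test that respects
heterogeneity and (b) a way to compare selection methods on real data
where the true differential genes are unknown.

## The method

Technical error is modelled as homogeneous across features and
heterogeneous across arrays. Within a cohort of *n* arrays, the
variance across features of the per-feature log2 differences between
arrays *r_i* and *r_j* estimates σ²(r_i) + σ²(r_j), giving the
samplewise error variances

    σ²(r_i) = 1/2 · 1/(n−1) · Σ_{j≠i} σ²(r_i, r_j).

After scaling normalization (additive per-array alignment to the
global geometric-mean level, which provably leaves the difference
variances untouched), each cohort's measurements are combined into the
precision-weighted Gaussian posterior of its true mean, and each
feature is tested with

    z = (μ_t − μ_c) / √(σ²_t + σ²_c),

two-sided normal p-values and Benjamini–Hochberg FDR. Because the
variance is shared across features, subtype-inflated per-feature
spread cannot demote a gene; with even array quality the |z| ranking
equals the fold-change ranking, and with uneven quality noisy arrays
are downweighted.

The package also provides the pooled t-test and hybrid-selection
baselines, Fisher-exact gene-set overrepresentation with a
link-disordering chance benchmark, a reliability benchmarking report
(relative specificity / sensitivity / reproducibility, disease-function
detection rate, AUC misanalysis flags), a progressive
permutation-degradation validation, and a simulator of type I
(genetically identical) and type II (molecularly heterogeneous)
cohorts with ground truth. See the vignette
`vignettes/heterogeneity-aware-testing.Rmd` for the full model and the
design decisions.

## Worked example

Simulate a heterogeneous contrast (two latent subtypes in the test
cohort), test it, and benchmark three methods across two data sets of
the same simulated study:

```r
library(hta)

cfg <- synthetic_config(n_features = 4000, n_test = 6, n_control = 6,
                        deg_fraction = 0.05, n_subtypes = 2,
                        subtype_block_size = 150, n_sets = 25, seed = 42)
ds <- simulate_type2(cfg)
de <- hta_test(ds$matrix, ds$design)
head(de[order(de$p), ], 3)
#>      feature    fc_hat     var_fc         z            p            q
#> 2964  f02964 -2.229239 0.01857605 -16.35611 3.935014e-60 1.574006e-56
#> 3031  f03031  2.041956 0.01857605  14.98200 9.628246e-51 1.925649e-47
#> 1684  f01684 -2.029427 0.01857605 -14.89007 3.823613e-50 5.098151e-47
```

Every feature shares the same fold-change variance (even array
quality), so the z ranking is the fold-change ranking. The estimated
samplewise error SDs (`sqrt(attr(de, "error_models")$test$sigma2)`)
come out near 0.267 against a generating technical SD of 0.2 — the
subtype blocks inflate the pairwise differences slightly, which is the
method's stated conservatism under heterogeneity.

```r
tt <- pooled_t_test(scaling_normalize(ds$matrix)$matrix, ds$design)
c(hta = sum(de$q < 0.05), ttest = sum(tt$q < 0.05))
#>   hta ttest
#>   443   191

sc <- simulate_study_collection(cfg, n_datasets = 2)
signal <- sc$truth$functions$function_id[sc$truth$functions$is_signal_set]
datasets <- lapply(sc$datasets, function(d)
  list(matrix = d$matrix, design = d$design))
rep <- bmorr_report(datasets, sc$collection,
                    methods = c("hta", "ttest", "hm"),
                    disease_functions = signal)
rep$per_dataset
#>  dataset method n_functions n_selected_fdr       rsp       rse auc misanalyzed
#>       d1    hta           6            443 1.0000000 1.0000000   1       FALSE
#>       d1  ttest           6            191 1.0000000 0.4311512   1       FALSE
#>       d1     hm           5            114 0.8333333 0.2144470   1       FALSE
#>       d2    hta           6            450 1.0000000 1.0000000   1       FALSE
#>       d2  ttest           6            181 1.0000000 0.4022222   1       FALSE
#>       d2     hm           4            119 0.6666667 0.1762963   1       FALSE
rep$per_method
#>  method        rr detection_rate
#>     hta 1.0000000           1.00
#>   ttest 1.0000000           1.00
#>      hm 0.9444444           0.75
```

Reading the report: `n_functions` is the count of gene sets
overrepresented (Fisher p < 0.001) in each method's p < 0.05
selection; `rsp`/`rse` are those counts and the FDR < 0.05 selection
sizes normalized by the reference method (here the z-test, pinned at
1 by construction); `rr` is cross-data-set reproducibility of detected
functions; `detection_rate` is the per-data-set average fraction of
the designated signal functions recovered. On this heterogeneous
contrast the z-test selects 2.3× more features at FDR < 0.05 than the
t-test — the relative-sensitivity gap (1.00 vs 0.43 vs 0.21) — and the
fold-change cutoff costs the hybrid method a quarter of the signal
functions.

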