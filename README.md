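# kplsmwmr

Supervised feature selection for high-dimensional biomedical classification
matrices (gene expression panels, proteomics, clinical feature tables):
kernel partial least squares (KPLS) latent mapping, ReliefF relevance
weighting, Pearson-correlation redundancy, and a greedy forward search over
the weighted maximum-weight / minimum-redundancy (MWMR) criterion

    R_j = alpha * w_j - (1 - alpha) * r_j,    alpha in [0, 1]

where `w_j` is the candidate feature's min–max normalized ReliefF weight
(computed on the rank-p KPLS reconstruction of the data) and `r_j` its
aggregated absolute Pearson correlation to the other features. `alpha = 1`
reduces to pure relevance ranking; small `alpha` emphasizes
redundancy removal. The package is for analysts who need a small,
interpretable feature subset feeding a downstream classifier, and it ships
everything needed to study the method offline: a Fisher-score baseline, a
three-class synthetic benchmark generator, and a repeated stratified
cross-validation harness (linear SVM, accuracy / Cohen's kappa / macro-F1)
with tidy() / glance() / autoplot() methods on every result type.

## Worked example

```r
library(kplsmwmr)

d <- synth_benchmark(seed = 42)      # 300 x 103: 3 informative + 100 noise features
fit <- kpls_mwmr(d, alpha = 0.3, k = 5)
fit
#> KPLS-MWMR pipeline fit
#> Kernel PLS fit: 300 samples, 103 features, 3 classes
#>   components: 10 (converged: 10)  kernel width s = 73.5148
#> MWMR selection: k = 5, alpha = 0.3 (redundancy: mean pool)
#>    f2, f3, f1, f92, f28

tidy(fit)
#> # A tibble: 5 x 7
#>    step pool_size feature weight raw_weight redundancy criterion
#>   <int>     <int> <chr>    <dbl>      <dbl>      <dbl>     <dbl>
#> 1     1       103 f2       1          0.445     0         0.3
#> 2     2       102 f3       0.987      0.440     0.0556    0.257
#> 3     3       101 f1       0.939      0.420     0.0457    0.250
#> 4     4       100 f92      0.408      0.202     0.0435    0.0919
#> 5     5        99 f28      0.398      0.198     0.0434    0.0890
```

The trace reads step by step: the three informative features `f1`–`f3` are
picked first — large ReliefF weights, modest redundancy to the rest of the
pool — and only then the best noise features, whose criterion drops by a
factor of ~3. Evaluating the top three features:

```r
cv <- cross_validate(d, features = selected_features(fit)[1:3], seed = 42)
cv
#> Cross-validation (10 x 10-fold, linear SVM (C = 1), select_once mode)
#>   accuracy 1.0000 +/- 0.0000 | kappa 1.0000 | macro-F1 1.0000
```

The benchmark's class means (5 / 10 / 15, sd 1) are five standard
deviations apart, so a linear SVM on the recovered informative features is
essentially error-free. `autoplot()` works on the fit, the weights, the CV
result and on `alpha_sweep()` tables; `within_fold` mode re-runs selection
inside each training split when a leakage-safe estimate is wanted. See the
methods vignette (`vignettes/kpls-mwmr-methods.Rmd`) for the model,
parameter guidance, and design decisions.

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "kplsmwmr", package = "kplsmwmr")`:

```sh
kplsmwmr synth --seed 42 -o synth.csv
kplsmwmr select --data synth.csv --label-col class --alpha 0.3 --k 10 -o report.json
kplsmwmr evaluate --data synth.csv --report report.json --folds 10 --repeats 10
kplsmwmr sweep-alpha --data synth.csv --alphas 0.1:0.9:0.1 --k 3 -o sweep.csv
```

Matrices are CSV/TSV with a header row, samples in rows, features in
columns, one label column; reports are JSON with full provenance.

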