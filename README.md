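# msldSampEn

Classification of single-channel epileptic EEG by sample entropy on the
Multidistance Signal Level Difference (MSLD) transform.

EEG from an epileptic seizure (ictal) is highly irregular; EEG between
seizures (interictal) is the most regular; healthy-subject EEG sits in
between. This package turns that complexity contrast into a classifier
for researchers working with single-channel EEG records: it computes,
for each record, the family of absolute-difference signals

    y_d(i) = | x(i) - x(i + d) |,   i = 1 .. N - d,   d = 1 .. K,

and the sample entropy of each difference signal

    SampEn(m, r, N) = -ln(A / B),

where `B` counts template pairs of length `m` matching within tolerance
`r·SD` under the Chebyshev norm (self-matches excluded) and `A` the
pairs still matching at length `m + 1`. The K-dimensional entropy
profile (default K = 20, m = 2, r = 0.25) is the feature vector; a
soft-margin SVM with linear, quadratic or cubic kernel classifies it
under stratified 5-fold cross-validation. A grid driver sweeps
r ∈ {0.1, 0.15, 0.2, 0.25} × scale ranges {1–20, 1–15, 1–10, 1–5} ×
the three kernels.

Inputs are plain ASCII records, one amplitude per line (the dialect of
the public three-class epilepsy EEG archive: 4096 samples per record at
173.61 Hz — 23.6 s). A seeded synthetic generator provides a
three-class stand-in set with the same complexity ordering, so the full
pipeline runs without any download.

## Worked example

```r
library(msldSampEn)

set <- gen_labeled_set(n_per_class = 20, n_samples = 4096, seed = 1)
tab <- extract_feature_table(set, d_min = 1, d_max = 20,
                             sampen_params(m = 2, r = 0.25))

# per-class mean entropy at a few distances
agg <- aggregate(feature_matrix(tab)[, c(1, 5, 10, 20)],
                 list(class = tab$label), mean)
agg[-1] <- round(agg[-1], 2)
agg

cross_validate(tab, kernel_by_name("cubic"), n_folds = 5, seed = 1)
```

```
            class sampen_d1 sampen_d5 sampen_d10 sampen_d20
1      ictal-like      1.73      1.76       1.77       1.77
2 interictal-like      0.48      0.35       0.32       0.33
3     normal-like      1.51      0.88       0.68       0.56
<msld_cv> 5-fold, mean accuracy 100.0% (folds: 100.0, 100.0, 100.0, 100.0, 100.0)
                 predicted
true              ictal-like interictal-like normal-like
  ictal-like              20               0           0
  interictal-like          0              20           0
  normal-like              0               0          20
```

The first table is the complexity profile: seizure-like records keep
near-noise entropy (~1.77) at every distance, the smooth interictal-like
class stays lowest, and the normal-like class lies between — the
ordering that makes the three classes separable. The cross-validation
report shows per-fold and mean accuracy and the pooled confusion matrix
(here the synthetic classes are fully separated).

The same workflow from a shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli/msld-sampen.R", package = "msldSampEn"))')
Rscript "$cli" simulate --out signals --n-per-class 20 --seed 1
Rscript "$cli" extract  --data signals --out features.csv --r 0.25
Rscript "$cli" classify --features features.csv --out report.json --kernel cubic
Rscript "$cli" grid     --data signals --out-dir grids
```

`extract` works identically on a directory of real archive records
(one subdirectory per class).

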