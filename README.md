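# bcicalib

Shortening the calibration session of subject-specific classifiers of neural
and physiological data.

Passive brain-computer interfaces and physiological computing systems (for
example, recognising the difficulty of a task from EEG band powers,
electrodermal activity, respiration and ECG features) suffer from large
individual differences: models trained on other people transfer near chance,
and models trained on the user alone need a long calibration session. This
package implements a collaborative-filtering approach to cut that session
short, for kNN and RBF-SVM classifiers:

* **Transfer learning (TL)** — hyperparameters (the neighbour count `k`, or
  `(C, gamma)`) are selected by leave-one-out cross-validation on the user's
  own `m` samples; because ties are ubiquitous at small `m`, they are broken
  by the accuracy of the user-trained classifier on the most similar database
  subject's data, used as validation samples. Similarity between subjects
  `p, q` is the mean squared difference of per-class mean feature vectors,
  `d(p, q) = mean_c mean_f (m̄_c^p[f] − m̄_c^q[f])²` over shared classes.
* **Active class selection (ACS)** — the class of the next online training
  sample is requested with probability proportional to the inverse of that
  class's current per-class LOOCV accuracy, `p_c ∝ 1 / max(a_c, ε)`, with the
  improvement that no two consecutive requests may name the same class.
* **TL+ACS** — both in one calibration loop: start with one sample per class,
  each iteration re-select the donor subject, select parameters with the TL
  tie rule, then request the next `l` samples from ACS-chosen classes, until
  the internal accuracy reaches `λ` or `m = 30`.

The package also ships the 29-feature extraction pipeline for raw
multichannel recordings (EDA/RSP min-max-mean, ECG beats and inter-beat
interval, theta/alpha/beta power at seven EEG sites, EOG regression,
per-subject min-max normalization), a synthetic multi-subject pool generator
with clustered inter-subject structure, and an evaluation harness producing
leave-one-subject-out learning curves, samples-saved percentages, paired
t-tests and Holm-corrected significance flags. See the vignette
`vignettes/calibration-methods.Rmd` for the full methodology.

## A worked example

```r
library(bcicalib)

pool <- generate_pool(pool_spec(seed = 2024))   # 18 subjects x 150 epochs x 29 features
src  <- make_label_source(attr(pool, "models")[["S01"]], seed = 7)
cfg  <- calibration_config(n_classes = 3, classifier = "knn",
                           use_tl = TRUE, use_acs = TRUE, seed = 7)
st   <- run_calibration(src$source, subject_pool(pool[-1]), cfg, test = src$test)
st
#> <calibration_state> m = 30, acc_cv = 0.833
#>   params: k=15
tail(st$iteration_log[, c("m", "acc_p", "acc_a", "k", "acc_test")], 3)
#>     m     acc_p     acc_a  k  acc_test
#> 26 28 0.8571429 0.7666667  9 0.8733333
#> 27 29 0.8275862 0.8333333 11 0.8866667
#> 28 30 0.8333333 0.8666667 15 0.8866667
```

`m` is the number of user-specific samples collected so far, `acc_p` the
internal LOOCV accuracy driving selection, `acc_a` the auxiliary validation
accuracy used to break ties, and `acc_test` the accuracy on 150 held-out
epochs of the same subject — the quantity a learning curve tracks.

A command-line interface wires the same steps together (`exec/bcicalib`):

```sh
bcicalib simulate-pool --seed 7 --out pool.csv
bcicalib calibrate --pool pool.csv --subject S01 --method tl_acs --out cal.json
bcicalib evaluate --pool pool.csv --repeats 10 --out curves
bcicalib compare --curves curves.json --out comparison
```

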