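# harselect

Human locomotion classification (stand, walk, sit, lie) from body-worn
3-axial accelerometer and IMU streams, trained on a *small, automatically
selected* subset of the session instead of the usual bulk split.

## Who this is for

Anyone working with multi-sensor wearable recordings who needs a
per-sample activity classifier but cannot afford (or does not want) to
train a kernel machine on hundreds of thousands of labeled rows. The
package also ships a seeded synthetic session generator that emulates the
statistical structure of such recordings — posture-dependent gravity,
gait-band oscillation, sensor noise, bursty missing data — so the whole
method can be exercised and tested without any external dataset.

## The method

A session with `k` sensors is an `n x 3k` acceleration matrix with one
label per row. After per-channel imputation and denoising (band-pass FIR,
order 40, 2–15 Hz, followed by wavelet soft-thresholding with the
universal threshold `λ_j = σ_j √(2 ln N_j)`, `σ_j` estimated by
`median(|ω|)/0.6745`), three kinematic feature groups are built per row —
the signal magnitude vector `|a_{j,k}|`, the axial-ratio roll/pitch/yaw
angles, and the axial component matrix — and each is compressed to two
components by PCA and by uncentered SVD, giving 12 features `f1…f12`.

The core is the candidate selection. For a feature pair `(f_j, f_k)` and
every ordered pair of distinct classes `(n, m)`, each member `x` of class
`n` is scored by its Euclidean distance to the opposite class centroid,

    R_{n,m}(x) = || x − centroid_m ||,

and is kept as a training candidate when

    R_{n,m}(x) ≥ mean(R_{n,m}) + σ(R_{n,m}).

The union over all ordered class pairs is the pair's *vector of
candidates* (VoC) — typically 8–15% of the session. A one-vs-all RBF SVM
is trained on the VoC (min-max normalized with candidate-only bounds),
with `(C, γ)` chosen from the grid `2^-5 … 2^7` by stratified 5-fold
cross-validation; the whole session is then classified. All 66 feature
pairs are swept and the pair with the highest accuracy wins. A stratified
80/20 supervised fit on the same pair serves as the reference, and both
are compared on accuracy (Acc), training size (TS) and weighted F1.

## A worked example

```r
library(harselect)

cfg <- synth_config(layout = har_layout(2, 3), duration_s = 60, seed = 42)
out <- run_pipeline(cfg,
                    config = svm_config(c_exponents = seq(-5, 7, by = 3),
                                        gamma_exponents = seq(-5, 7, by = 3)),
                    seed = 42)
out$report
```

```
<har_report>
  iterative: Acc 85.56%  TS 8.22%  F1 0.8524
  baseline : Acc 89.72%  TS 80.00%  F1 0.8882
  gap (baseline - iterative): 4.17 points; TS ratio 9.7x
```

Reading: on a 1,800-row synthetic session the iterative model trained on
8.2% of the rows (the selected candidates) and classified the session at
85.6% accuracy — 4.2 points below a conventional supervised model that
needed 80% of the rows, i.e. ten times as much training data. The
`out$iterative` object is an ordinary fitted model with `print`,
`summary`, `predict` and `plot` methods; `out$iterative$table` holds the
per-feature-pair sweep results.

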