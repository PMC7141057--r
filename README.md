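# overlapfrp

Estimation of overlapping evoked potentials from co-registered continuous
neural recordings (EEG) and event streams (stimulus onsets, ocular fixation
onsets).

## The problem

Eye-fixation-related potentials (EFRPs) are evoked responses time-locked to
fixation onsets during free viewing. Inter-fixation intervals (~300 ms) are
shorter than the evoked response itself, so neighboring responses superpose
inside every epoch and the classical time-locked average is biased: in the
noise-free limit

    â_Av(t) = Σ_f  Q_f(t) * a(t)

where `a(t)` is the underlying kernel, `Q_f` the normalized lag distribution
of the fixations at rank offset `f` from the lock (`Q_0` a unit impulse),
and `*` discrete convolution. The package implements, on a common epoching
and windowing layer, the three classical estimators of `a(t)`:

* **averaging** — the biased baseline, plus its exact overlap decomposition
  `Σ_f Q_f * a` used as an analytic oracle;
* **ADJAR** — the iterative adjacent-response correction
  `â(k) = â_Av − Q_-1 * â(k−1) − Q_+1 * â(k−1)`, with per-iteration Tukey
  tapering and baseline re-referencing, a relative-power stopping
  criterion, and second-order overlap diagnostics
  `ov_pp = Q_-1^(*2) * â`, `ov_ss = Q_+1^(*2) * â` that delimit its
  validity regime;
* **GLM deconvolution** — sparse stacked-Toeplitz designs `x = D a + n`
  with one column block per event class (one / two / three-class
  stimulus-onset configurations), solved by least squares, with Gram
  condition-number (`cond(D†D)`; exactly 1 for the averaging design) and
  bootstrap-variance diagnostics.

A synthetic session generator (ground-truth kernels as Gaussian-bump sums,
truncated-normal oculomotor timing, strictly linear superposition, optional
white/AR(1) noise) makes every estimator testable by parameter recovery.
See the vignette in `vignettes/overlap-correction.Rmd` for the model,
design choices and limitations.

## Worked example

Simulate 20 free-viewing trials with overlapping fixation responses and
AR(1) noise (sd 5 µV), then run all three estimators on identical epochs:

```r
library(overlapfrp)
fx  <- make_fixture("mid_exploration", seed = 7, n_trials = 20,
                    noise = noise_model("ar1", sd_uV = 5,
                                        ar_coefficient = 0.7))
rep <- compare_methods(fx)
print(rep)
#> <comparison_report 'mid_exploration' >
#>   average  baseline var 0.6185, tail dev 0.7343, RMSE 0.962
#>   adjar    baseline var 0.5421, tail dev 1.189, RMSE 1.111
#>   glm      baseline var 0.1097, tail dev 0.3732, RMSE 0.3933
```

Reading the numbers: `baseline var` is the variance of the estimate over
the [-200; -100] ms baseline (a stable estimate is flat there), `tail dev`
the mean absolute amplitude over [450; 600] ms (the response should have
returned to zero), and `RMSE` the error against the ground-truth kernel
over the [-250; 600] ms window of interest — computable only because the
fixture is synthetic. GLM deconvolution, which models all events in every
epoch, beats both the average and ADJAR on all three metrics; ADJAR
converged (11 iterations) but remains biased by the second-order overlaps
its first-order model ignores, which is the regime this fixture creates.

A thin command-line front end over the same functions ships in
`inst/cli/overlapfrp`:

```sh
inst/cli/overlapfrp simulate --preset mid_exploration --trials 50 --seed 7 --out sim/
inst/cli/overlapfrp estimate --preset mid_exploration --method glm --seed 7 --out kernel.txt
inst/cli/overlapfrp compare  --preset mid_exploration --seed 7 --out report.json
```

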