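---
title: "Estimating overlapping evoked potentials: averaging, ADJAR and GLM deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating overlapping evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapfrp)
```

## The problem

When EEG is co-registered with eye tracking, the response of interest is
often time-locked to an ocular fixation onset (an eye-fixation-related
potential, EFRP) rather than to a stimulus. Under free viewing, consecutive
fixations follow each other every ~300 ms — shorter than the duration of the
evoked response itself — so the potentials elicited by neighboring fixations
superpose linearly on the potential elicited by the fixation one is trying
to estimate. The classical estimator, the time-locked average across
epochs, is then biased: its noise-free expectation is not the kernel
$a(t)$ but

$$\hat a^{Av}(t) = \sum_f Q_f(t) * a(t),$$

where $Q_f$ is the distribution (normalized by the number of epochs $E$) of
the onsets of the fixations at rank offset $f$ from the lock, $Q_0$ is a
unit impulse at zero lag, and $*$ is discrete convolution. The bias terms
$Q_f * a$ for $f \ne 0$ do not vanish as $E$ grows. `overlapfrp` implements
this identity, the two classical corrections — the ADJAR adjacent-response
iteration and linear-model (GLM) deconvolution — and a synthetic session
generator so each estimator can be validated by parameter recovery.

## Windows and conventions

Three nested intervals organize every analysis (all are `time_window`
objects with inclusive endpoints, so a window $[t_0; t_1]$ at rate $f_s$
holds $(t_1 - t_0) f_s / 1000 + 1$ samples):

* **window of interest** — what is reported; for fixation-locked analyses
  $[-250; 600]$ ms (851 samples at 1000 Hz).
* **estimation window** — where a kernel is estimated; equal to the window
  of interest for averaging and GLM, enlarged by a margin (default 200 ms,
  giving $[-450; 800]$ ms) for ADJAR to absorb convolution border effects.
* **epoch window** — the segment cut around each lock event; for the
  correction methods it must cover the responses of the adjacent fixations,
  so it is the window of interest padded on both sides by
  $\tau = \mathrm{mean}(IFI) + \mathrm{sd}(IFI)$ of the session
  (`epoch_window_for_participant()`), where the inter-fixation interval
  (IFI) is the onset-to-onset spacing of consecutive fixations. With
  $\tau \approx 410$ ms this yields $[-660; 1010]$ ms, 1671 samples.

Event onsets live on the sample grid; quantization rounds half up, which
keeps epoching and design construction bit-stable. Baseline correction
subtracts the mean over $[-200; -100]$ ms — after the previous fixation's
saccade, before the pre-lock saccadic spike — and `baseline_variance()` /
`tail_deviation()` score estimates by their stability there and their
return to zero late in the window.

Epochs whose window would cross the recording edge are rejected (with a
logged count) on the averaging path; the GLM design instead truncates
response stripes at epoch borders, so partial evidence is still used.
The per-epoch event lists keep *all* same-trial events, including those
just outside the epoch window: their response tails still reach into it,
and both the overlap identity above and the deconvolution design need them
to be exact.

## The estimators

**Averaging** (`average_epochs()`) is the pointwise mean. Its analytic
decomposition (`overlap_decomposition()`) convolves each lag distribution
with a kernel at full support and crops afterwards, so the border samples
of the cropped window are exact; this doubles as the oracle used in the
test suite.

**ADJAR** (`run_adjar()`) assumes the same kernel at every fixation and
that only the immediately adjacent fixations overlap. It iterates

$$ov_p^{(k)} = Q_{-1} * \hat a^{(k-1)}, \quad
  ov_s^{(k)} = Q_{+1} * \hat a^{(k-1)}, \quad
  \hat a^{(k)} = T\,B\,(\hat a^{Av} - ov_p^{(k)} - ov_s^{(k)}),$$

with both overlap terms computed from the same previous iterate
(Jacobi-style update), $T$ a Tukey taper (cosine ramps, default 200 ms,
equal to the estimation margin so the window of interest sits in the flat
region) and $B$ the baseline re-reference. Iterations stop when the
relative power $\|\hat a^{(k)} - \hat a^{(k-1)}\|^2 / \|\hat a^{(k-1)}\|^2$
drops below `stop_threshold` (default $10^{-5}$; the criterion's form is
standard, the value is a package choice). Convergence is tracked per
channel and the reported iteration count is the maximum; each channel's
estimate is frozen at the iterate the criterion found stable, so with an
infinite threshold the initialization — the (re-referenced) average — is
returned unchanged.

Two design choices deserve emphasis:

* *Baseline re-referencing inside the loop.* The two adjacent-fixation
  distributions each carry unit mass, so their sum has gain ~2 at zero
  frequency: a constant offset would roughly double at every iteration,
  and the raw iteration has an amplifying DC mode (the package's tests
  exhibit it). Evoked-potential data carry no DC information —
  acquisition is high-pass filtered and estimates are reported relative
  to a baseline — so each iterate is re-referenced to its
  $[-200; -100]$ ms mean. This removes the non-physical mode and makes
  the iteration contractive in the regimes studied here; it can be
  disabled with `adjar_config(baseline = NULL)`, which reproduces the
  divergence.
* *Validity regime.* Even when the iteration converges, its fixed point
  is unbiased only if the second-order supports $Q_{\pm 1} * Q_{\pm 1}$
  carry no mass inside the estimation window. `second_order_overlaps()`
  reports the corresponding diagnostics
  $ov_{pp} = Q_{-1}^{(*2)} * \hat a$ and $ov_{ss} = Q_{+1}^{(*2)} * \hat a$.
  In the heavy-overlap regime the recovered-vs-true residual is aligned
  with $+(ov_{pp} + ov_{ss})$: the data's own rank-$\pm 2$ overlap
  survives the first-order fixed point with positive sign (expanding
  $(I + Q_{-1} + Q_{+1})^{-1} \sum_f Q_f\, a$ to second order leaves
  $+ (Q_{-1}^{(*2)} + Q_{+1}^{(*2)})\,a$, the mixed products cancelling),
  while higher mixed orders pull the other way. A truncated development
  of the iteration instead suggests the opposite sign; the fixed-point
  sign is what the package's parameter-recovery tests measure.

**GLM deconvolution** (`build_design()` + `solve_glm()`) models every
event inside every epoch. Each model class (a class label plus an optional
rank range, `glm_class()`) contributes one column block — one column per
lag of its estimation window — and every matched event writes a diagonal
stripe of ones into the sparse design $D$ (stacked Toeplitz blocks,
epoch-major rows). The estimate is the least-squares solution
$\hat a = \arg\min \|x - Da\|^2$. The solver forms the Gram matrix
$D^\dagger D$ sparsely and uses its Cholesky factor: the Gram is small
(one row/column per estimated lag) while $D$ has one row per recorded
sample, and at the condition numbers these designs reach (up to ~$10^3$,
squared to ~$10^6$ in the Gram) double precision loses only a handful of
digits — parameter-recovery tests on noiseless fixtures confirm errors
near $10^{-10}$ µV. A rank-deficient design (e.g. duplicated classes)
falls back to the eigendecomposition pseudo-inverse, returning the
minimum-norm solution with `rank_deficient = TRUE`. Channels share the
design and are solved jointly.

Canonical stimulus-onset configurations come from `onset_model_classes()`:
one class (the averaging analogue), two classes (stimulus kernel over the
whole epoch + one fixation kernel for all ranks) and three classes
(stimulus + first fixation + subsequent fixations, the first fixation
having its own ocular and image statistics). With $N_s$ stimulus lags and
$N_a$ fixation lags the three-class design has $N_s + 2 N_a$ columns.

Two diagnostics qualify an estimate: `gram_condition_number()` — the
2-norm condition number of $D^\dagger D$, exactly 1 for the averaging
design and growing as event-timing jitter falls — and
`bootstrap_variance()`, which resamples epochs with replacement (the
trial-level unit), re-solves per replication (10 000 by default) and
reports per-sample variance curves per class. Replications that leave a
class without events are redrawn with a capped retry count. On
onset-locked sessions the stimulus-kernel variance orders
three-class ≥ two-class ≥ averaging: each added class spends the same
data on more parameters. That is the bias–variance trade-off the model
choice must negotiate.

## The synthetic generator

`make_fixture()` builds complete ground-truth sessions: kernels are sums
of Gaussian bumps (`kernel_spec()`; the default fixation kernel has a
lambda-like positivity peaking at 100 ms, the stimulus kernel P1/P2-like
components), fixation sequences come from truncated-normal first-latency
and IFI draws (`oculomotor_model()`, floor 50 ms, 4-s trials), and
`render_session()` superposes kernels at event onsets strictly linearly,
plus optional white or AR(1) noise of chosen marginal sd (AR(1) as a
crude stand-in for temporally correlated ongoing activity).

`oculomotor_model()` defaults quote session summaries typical of free
scene exploration — first-fixation latency 307.65 (46.14) ms, IFI
288.69 (26.97) ms. Those printed dispersions are between-participant
(spreads of participant means); a single participant's IFI distribution
is much wider. The `mid_exploration` preset therefore sets the IFI sd to
117.68 ms, the within-participant spread implied by
$\tau = 406.37$ ms $= \mathrm{mean} + \mathrm{sd}$ of the individual IFI
distribution; with it the generated sessions reproduce the ~$[-660;1010]$ ms
epoch window and ~5.8 fixations per epoch, and the ADJAR operator's
contraction behavior matches the reported iteration counts. Both spreads
remain exposed as parameters.

Presets: `mid_exploration` (single fixation kernel, locks drawn uniformly
from ranks 3–9, three draws per trial with replacement — duplicates
collapse with a note), `onset_two_class` / `onset_three_class`
(stimulus-locked, with shared or rank-split fixation kernels), and
`first_order_only` (slow regular scanpaths, IFI 650 (20) ms, lock at rank
3, built so each epoch holds exactly one previous and one subsequent
fixation and the second-order lag supports miss the $[-450; 800]$ ms
estimation window — ADJAR's validity regime by construction). All
randomness flows through one seed per call; fixtures are bit-identical
under a fixed seed. `write_fixture()` emits the event CSV, a plain-text
recording container and a JSON sidecar with the true kernels and seeds.

What the generator does *not* emulate: scalp topographies and volume
conduction (channels are scaled copies), saccadic spike artifacts,
amplitude modulation of the kernel by saccade size or local image
statistics, 1/f spectra beyond AR(1), and oculomotor serial dependence
(IFIs are i.i.d.). Passing recovery tests therefore demonstrates
correctness of the estimators under linear superposition — the model all
three methods assume — not robustness to everything real sessions add.

## Problem sizes used in the checks

The test suite and acceptance script keep the study conditions (trial
counts, noise sd 5 µV AR(1), ranks 3–9, window definitions) and scale
computation elsewhere: exact-identity checks run at 1000 Hz with 10–30
trials; the 100-session unbiasedness sweep runs at 200 Hz with 50 trials
per session; bootstrap comparisons run at 100 Hz with 1000 replications
(the methodology's reference count is 10 000; the ordering is stable well
below that). These sizes are the package's choices for routine
verification and are stated here so they can be scaled up when desired.

## Known limitations

* ADJAR is implemented in its first-order form; variants that model
  non-adjacent events are out of scope (the iterative scheme is known not
  to converge there).
* No regularized (ridge) deconvolution and no continuous covariate
  modulation (spline/GAMM expansions); classes are discrete.
* The bootstrap resamples epochs, not participants; multi-participant
  inference is out of scope.
* `gram_condition_number()` densifies the Gram matrix; for very long
  estimation windows at high sampling rates it is the slow path.
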