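---
title: "Interpreting EEG deep-learning classifiers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting EEG deep-learning classifiers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegattr)
```

## The problem

A convolutional network trained on multichannel EEG produces a class score
$S_c(x)$ for a sample $X \in \mathbb{R}^{N \times T}$ ($N$ channels, $T$
sampling points, microvolts). An attribution (contribution) map
$R_c \in \mathbb{R}^{N \times T}$ assigns each sampling point a score
quantifying its contribution to $S_c$; averaging $R_c$ over time gives a
per-electrode channel contribution map. Attribution maps are widely used to
argue that a BCI model has learned neurophysiology (sensorimotor rhythm
desynchronization, feedback-related negativity, alpha spindles) rather than
artifacts (blinks, EMG, loose electrodes) — but a map is only evidence if it
faithfully tracks the model. `eegattr` packages three things: the attribution
methods, quantitative faithfulness tests that decide whether a given map can
be trusted, and a sample-wise trust report that presents both together.

## One engine, seven methods

Every layer computes an affine map $z_j = \sum_i w_{ji} x_i + b_j$ followed by
an elementwise nonlinearity $x_j = f(z_j)$. All seven methods are gradients of
$S_c$ in which the local factor at each nonlinearity, normally $f'(z)$, may be
replaced by a rule-specific factor $g$:

| method | map | factor at nonlinearities |
|---|---|---|
| saliency | $\partial S_c/\partial x_i$ | $f'(z)$ |
| deconvolution | $\partial_g S_c/\partial x_i$ | $f'(z)\,[f'(z)>0]$ |
| guided backprop | $\partial_g S_c/\partial x_i$ | $f'(z)\,[f'(z)>0]\,[f(z)>0]$ |
| gradient × input | $x_i \cdot \partial S_c/\partial x_i$ | $f'(z)$ |
| integrated gradients | $(x_i-\bar{x}_i)\cdot \overline{\partial S_c/\partial x_i}$ along the path | $f'(z)$ |
| LRP (ε-rule) | $x_i \cdot \partial_g S_c/\partial x_i$ | $f(z)/(z + \varepsilon\,\mathrm{sign}\,z)$ |
| DeepLIFT (rescale) | $(x_i-\bar{x}_i)\cdot \partial_g S_c/\partial x_i$ | $(f(z)-f(\bar z))/(z-\bar z)$ |

with $\bar{x}$ the all-zero baseline (the default) and $\bar z$ the
pre-activations from a second forward pass on the baseline.

Notes on the exact forms implemented:

* **Deconvolution / guided backprop** are implemented with the forward-side
  gates shown above. A widely used alternative formulation of deconvolution
  gates on the sign of the *backward* signal instead; the two differ for
  general nonlinearities. The forward-gated form is the one whose linear-case
  algebra underlies the two-group analysis below, and for ReLU it makes
  deconvolution and guided backprop coincide with the plain saliency
  gradient. Users should treat these methods as diagnostic baselines, not as
  trustworthy attributions — that is exactly what the faithfulness tests
  show.
* **LRP ε-stabilizer.** The default is $\varepsilon = 10^{-9}$
  (`attribution_config(lrp_epsilon=)`), with $\mathrm{sign}(0) = +1$. The
  stabilizer perturbs the map by a relative $O(\varepsilon/z)$; at $10^{-9}$
  the identity "ε-LRP ≡ gradient × input on ReLU-only networks" holds to
  about $10^{-7}$, comfortably inside the $10^{-5}$ contract the test suite
  asserts.
* **DeepLIFT degeneracy.** Where $|z - \bar z| < \varepsilon$ the rescale
  factor is $0/0$; the implementation falls back to $f'(z)$, its limit.
* **Integrated gradients** averages plain gradients at the path *midpoints*
  $\bar x + \frac{k - 1/2}{m}(x - \bar x)$, $k = 1..m$, $m = 100$ by default.
  The midpoint rule is second-order accurate, so the completeness identity
  $\sum R_c = S_c(x) - S_c(\bar x)$ holds to ~$10^{-5}$ relative at 100
  steps; a right-endpoint sum needs an order of magnitude more steps for the
  same accuracy.
* **Batch normalization** is linearized for attribution:
  `freeze_batch_stats()` captures mean and variance from one forward pass of
  a reference batch and the layer becomes a fixed affine map, so a sample's
  map does not depend on its batch companions. Maps on an unfrozen model fall
  back to the running statistics accumulated during training.
* **Pooling adjoints**: mean pooling distributes gradients uniformly; max
  pooling routes to the argmax, first index on ties. Stock architectures use
  mean pooling, which keeps DeepLIFT's summation-to-delta exact.
* **Indexing** is 1-based throughout (channel 1 is the first payload row), as
  in all of R.

### Why the methods split into two groups

On a purely linear model $f(z) = z$, gradient × input, integrated gradients,
ε-LRP and DeepLIFT all reduce to $w_{ji} x_i$, which moves one-for-one with
the score when $x_i$ is perturbed. Saliency, deconvolution and guided
backprop reduce to the constant $w_{ji}$, independent of the input — zeroing
a patch changes the score by $\sum w_{ji}x_i$, which a constant map cannot
track. The faithfulness tests quantify exactly this: on the trained synthetic
task the first group's median sensitivity correlation is ≈ 0.97 at every
patch fraction while the second group's and the random baseline's hover near
zero, and the first group's deletion AUC beats a random map in 100/100 paired
draws (numbers recomputed by `scripts/acceptance.R`).

## Faithfulness tests

**Local-patch sensitivity** (`sensitivity_test()`): perturb the sample 100
times, each time zeroing a single patch of length $n$ in one uniformly chosen
channel at a uniform start, and correlate $S_c(x) - S_c(x_{\text{pert}})$
(pre-softmax, on the predicted class) with the summed map scores inside the
patch. Patch lengths sweep fractions 0.1–0.5 of $T$ with
$n = \lfloor \text{fraction} \times T \rfloor$ — for a 254-point sample,
25–127 points. The channel-level variant zeroes each channel once and
correlates the $N$ score drops with the channel map. Zero-variance inputs are
flagged `undefined` rather than propagating `NaN`, and channel-level results
on fewer than 3 channels carry a `low_power` flag.

**Deletion** (`deletion_curve()`): rank all points by map score (descending;
ties broken by channel then time index for reproducibility), cumulatively
zero the top fraction over a grid (default 1%–100% in 1% steps; whole
channels in channel mode), and record the softmax probability of the
originally predicted class. A faithful map removes the decisive evidence
early: small area under the curve. The sensitivity Δ uses the pre-softmax
score while deletion uses the probability — the two scales the respective
protocols are defined on; `sensitivity_test()` exposes only the score-based
form, and both curve modes (cumulative, and one-shot channel removal via
`channel_removal_probability()`) are available because the report uses the
one-shot form.

The **random baseline** (`random_contribution_map()`) draws i.i.d.
uniform(−1, 1) scores. Any method worth reporting must beat it on both tests;
`benchmark()` automates the comparison with perturbation draws paired across
methods (seeds derived from sample content, so results are invariant to
sample order).

## The sample-wise trust report

Raw maps are too noisy to read. The visualization pipeline is fixed:
**normalize** (global z-score; a constant map is flagged degenerate),
**threshold** (drop standardized scores below the cutoff; defaults 2 for the
sample map and 1 for the channel map, i.e. "keep ≥ 2 SD evidence" — about
2.3% of a Gaussian map survives threshold 2), then **smooth** (centered
moving average along time, window 5; boundary windows shrink rather than
invent padding). `threshold_map()` refuses unnormalized input, so the order
cannot be permuted silently. Thresholding keeps positive scores only
(evidence *for* the predicted class) by default; a signed mode keeps both
polarities.

`generate_report()` then runs the sensitivity test on the *original* map (the
best local correlation the map can achieve) and the deletions on the
*processed* map (so the numbers refer to exactly the highlighted regions),
and emits a four-line text block: settings; sensitivity correlations; sample
deletion (new probability, deleted portion, top-3 channels by deleted-point
count, ties by channel index); channel deletion (new probability, removed
channels). The recorded probabilities equal re-running the model on the
explicitly deleted sample to $10^{-9}$ — asserted in the test suite.
`render_overlay()` draws the processed map as color intensity over stacked
signal traces with the report underneath.

## The synthetic task and what it does (not) show

No real EEG ships with ground truth about what a model should use, so the
package generates a two-class task with implanted, mask-annotated features on
a $1/f$ (pink-noise) background, 8 channels × 256 points at 128 Hz,
amplitudes in tens of µV (background SD 10 µV):

* class 1, "alert-like": broadband 25–45 Hz EMG-style bursts on
  temporal/frontal channels (1, 2, 7, 8);
* class 2, "drowsy-like": ~9–11 Hz alpha spindles under a raised-cosine
  (waxing-and-waning) envelope, 0.5–1.5 s, on central channels (3, 6);
* also available: `blink_pulse`, a 0.2–0.4 s monophasic frontal transient.

The feature amplitude is `snr` × background SD with `snr = 2` by default — a
prominent-but-not-dominant feature, comparable to a clear alpha burst over
ongoing EEG. Each feature is strictly supported on its mask (zeroing the
masked region leaves a pure background draw), onsets are uniform, per-sample
seeds derive deterministically from the dataset seed, and class proportions
follow `class_balance` with the rounding surplus assigned to class 1. The
classes are separable by construction (a logistic regression on alpha/EMG
bandpower exceeds 0.9 accuracy — the suite verifies this oracle before
asking the CNN to beat it), and `localization_score()` measures whether a
map's top points concentrate in the mask (1 = chance).

What passing these tests does *not* show: real EEG has correlated channels,
nonstationary background, feature families that overlap in frequency, and
label noise. The synthetic task validates the *machinery* — rules, tests,
report plumbing — not any neurophysiological claim about a real dataset.

## Reference models and trainer

Two stock architectures (`stock_architecture()`): temporal convolution (8
filters, kernel 17 ≈ 133 ms at 128 Hz) → batchnorm → cross-channel
convolution (8 filters) → batchnorm → ReLU (`"relu-compact"`) or ELU
(`"elu-compact"`) → mean pooling (window 8) → dense output. BN after each
convolution mirrors EEGNet-style designs and keeps optimization
well-conditioned for µV-scale inputs. The trainer is Adam
(η = 0.001, β₁ = 0.9, β₂ = 0.999 — the standard defaults), weighted
cross-entropy (weights handle class imbalance), batch statistics treated as
constants in the backward pass, running statistics kept with momentum 0.1,
and best-epoch selection by lowest validation loss on a held-out 20% split
(the selection criterion was an open choice; validation loss is the
conventional one). Training is bitwise reproducible from the config seed.

The default batch size is 50. For the 200-sample demo task that yields only
3 optimizer steps per epoch, so the worked examples train with
`batch_size = 10` (320 steps over 20 epochs), which reaches ≥ 0.95 held-out
accuracy in ~15 s on one CPU; problem sizes throughout the suite (200
training samples, 10 benchmark samples, 100 perturbations per sensitivity
configuration, 100 paired deletion draws) were chosen as the smallest that
make every qualitative contrast decisive.

## Numerical and degenerate-input policy

* Probabilities are softmax of the pre-softmax scores with max-subtraction;
  they sum to 1 within $10^{-9}$.
* Deletion tie-breaks, pooling argmax ties, and top-channel ties are all
  resolved by ascending index, so every result is reproducible bit-for-bit.
* Deleted-portion accounting is exact counting: zeroed points over $N\,T$.
* Degenerate cases are flagged, not silently propagated: zero-variance
  sensitivity vectors (`undefined`), constant maps (`degenerate`, deletion
  skipped in the report), < 3 channels (`low_power`).
* Checkpoints, samples and maps are plain text (JSON / delimited matrices at
  17 significant digits), which round-trips doubles exactly.

## Known limitations

* Only feed-forward stacks of the supported layer kinds; no recurrent or
  attention layers, and no occlusion/perturbation-family attribution methods
  (a deliberate scope choice — those treat the model as a black box).
* The channel maps average signed scores; strong positive and negative
  evidence on one electrode can cancel.
* Scalp topography rendering is out of scope; channel-level results are
  reported as named channels, not interpolated maps.
* The trainer is a demo trainer for desk-scale experiments, not a
  replacement for a production training loop.
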