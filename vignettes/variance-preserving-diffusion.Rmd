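---
title: "Variance-preserving variational diffusion for grayscale medical images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-preserving variational diffusion for grayscale medical images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VPDiffusion)
```

## The model and its assumptions

VPDiffusion implements a variational diffusion model (VDM) for grayscale
images. The forward process corrupts a clean tensor $x$ into latents $z_t$,
$t \in [0, 1]$, by Gaussian noising parameterised on the log-signal-to-noise
scale $\gamma(t)$:

$$q(z_t \mid x) = \mathcal N\!\left(\alpha_t x,\ \sigma_t^2 I\right),
  \qquad \sigma_t^2 = \mathrm{logistic}(\gamma(t)),
  \qquad \alpha_t^2 = 1 - \sigma_t^2 .$$

The variance-preserving constraint $\alpha_t^2 + \sigma_t^2 = 1$ makes the
signal-to-noise ratio $\alpha_t^2/\sigma_t^2 = e^{-\gamma(t)}$ strictly
decreasing whenever $\gamma$ increases, which every schedule in the package
guarantees. One source text for this model family writes the constraint as
$\alpha_t = 1 - \sigma_t^2$; taken literally that is not variance-preserving,
so the package implements the squared relation, the only reading consistent
with the variance-preserving process the model family is built on.

Because all conditionals are Gaussian, the transition
$q(z_t \mid z_s)$ and the Bayes posterior $q(z_s \mid z_t, x)$ have closed
forms; `marginalParams()`, `transitionParams()` and `posteriorParams()`
expose them and the test suite checks them against grid-quadrature Bayes
inversion and Monte-Carlo moments rather than against the implementation
itself.

Diffusion runs in a learned latent space: a dense-ResNet encoder maps the
flattened image to a 64-dimensional latent, a decoder maps latents back to
per-pixel Bernoulli *logits* (a mean-field observational model: the
likelihood factorises over pixels), and a FiLM-conditioned score network
predicts the injected standard-normal noise $\hat\varepsilon_\theta(z_t,
\gamma_t)$. The score network is interpreted as $\varepsilon$-prediction —
it "predicts the noise contained in the image" — rather than
$x_0$-prediction; this fixes the reverse step to

$$\hat x = (z_t - \sigma_t \hat\varepsilon)/\alpha_t, \qquad
  z_s \sim q(z_s \mid z_t, \hat x).$$

The reverse-time model in the source text also sketches a deterministic
inverse-map chain; that formulation conflicts with the Bayes-rule posterior
construction, so the package implements standard stochastic ancestral
sampling only (with a `temperature` knob; temperature 0 recovers the
posterior-mean trajectory).

## The objective

`totalLoss()` assembles four terms, reported in nats per image (sums over
pixels or latent dimensions, averaged over the batch):

* **Reconstruction** — Bernoulli negative log-likelihood of the intensities
  under the decoded logits of $z_0 \sim q(z_0 \mid x)$, computed in the
  stable logit form $\mathrm{softplus}(\ell) - x\ell$. Intensities in
  $[0,1]$ are treated as generalised Bernoulli targets.
* **Diffusion** — the continuous-time limit
  $\tfrac12\,\mathbb E\left[\gamma'(t)\,\lVert \varepsilon -
  \hat\varepsilon\rVert^2\right]$, estimated with *antithetic* times
  (exactly one per $1/n$ interval, one shared uniform offset). A discrete
  $T$-step variant with the exact $\mathrm{expm1}(\Delta\gamma)$ weighting
  is provided (`diffusionLossDiscrete()`); it equals the KL divergence
  between the $T$-step forward and reverse joints, is nonincreasing in $T$,
  and converges to the continuous value — all verified against an
  independent Gaussian-chain quadrature oracle.
* **Latent** — $\mathrm{KL}\!\left(q(z_1 \mid x)\,\Vert\,\mathcal N(0,
  I)\right)$ in closed form.
* **Differential** — mean squared mismatch of forward finite-difference
  image gradients between the image and its decoded mean, an edge-agreement
  penalty. Constant shifts are invisible to it by construction.

The source recipe names mean-squared error, KL divergence and differential
loss but reports "reconstruction / diffusion / latent" components; the
package reconciles the two lists as above (the MSE lives inside the
diffusion term, in $\varepsilon$-space). The weighting factors behind the
recipe's reported component values are unstated, so all four weights
default to 1 and are configurable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gammaMin`, `gammaMax` | 0.1, 1.0 | log-noise range; SNR spans $e^{-0.1} \approx 0.90$ to $e^{-1} \approx 0.37$ |
| `nGrid`, `nSubsteps` | 50, 1000 | tabulation grid of the schedule |
| `latentDim` | 64 | diffusion latent dimension |
| `encoderBlocks`, `decoderBlocks` | 6, 6 | residual blocks |
| `scoreEmbeddingDim`, `scoreLayers` | 128, 10 | score-net conditioning width and depth |
| `imageSize` | 256 | pixels per side (16–32 recommended on CPU) |
| `baseLR`, `warmupSteps`, `finalDecay` | 8e-4, 250, 1e-5 | AdamW schedule factors |
| `b1`, `b2`, `eps`, `weightDecay` | 0.9, 0.99, 1e-8, 1e-4 | AdamW settings |
| `batchSize`, `totalSteps` | 64, 20000 | optimisation scale |
| sampler `nSteps` | 5 (`fast`) / 20000 (`paper`) | reverse steps |

The printed $\gamma \in [0.1, 1.0]$ range is unusually narrow: at $t = 1$
the latent keeps substantial signal ($\alpha_1^2 \approx 0.27$), so the
$N(0, I)$ prior does not match $q(z_1)$ well. The package keeps the printed
range as the default (it is what the recipe states) but the range is fully
configurable, and the sampler-correctness tests use a wide range
$(-10, 10)$ where the prior-match assumption actually holds — that choice
is what makes "distribution recovery" a well-posed check of the sampler
rather than of the schedule.

Two printed values conflict elsewhere in the recipe: batch size (1 vs 64)
and learning rate (1e-4 vs 8e-4). Defaults follow the optimizer and
architecture paragraphs (64, 8e-4). Likewise the stated reverse-step counts
(5 vs 20,000) both survive as the `fast` and `paper` CLI presets.

## Learned monotonic schedule

`learnedGammaSchedule()` wraps a monotone network: a dense layer whose
weights pass through a softplus reparameterisation feeding sigmoid units,
plus a strictly positive linear term, affinely rescaled so that
$\gamma(0) = \gamma_{\min}$ and $\gamma(1) = \gamma_{\max}$ exactly.
Monotonicity is therefore *structural* — it holds for arbitrary, not just
trained, parameters, and the tests check 100 random parameter draws on
1000 sorted times with zero tolerance for violations. Training keeps the
linear schedule fixed by default: learning the schedule end-to-end would
require differentiating the $\gamma'(t)$ weighting through the schedule
network, which the reference recipe never exercises numerically; the
learned variant is provided as a drop-in schedule object.

## Synthetic phantoms: what a green test does and does not establish

`generatePhantoms()` emulates the *statistical shape* of frontal chest
radiographs: a smooth vertical background gradient, two bright elliptical
lung fields with seeded position/shape jitter, darker curved rib-like bands
crossing the lungs (7 by default), additive Gaussian noise (sd 0.02), all
clipped to $[0, 1]$ with the clip fraction recorded (well under 1% at
default noise). Defaults mirror the training regime the phantoms stand in
for: 1341 images at 256×256 — the published subset size of the NIH chest
X-ray collection — although CPU-scale tests use 16×16 and 200 images.

The phantoms are *not* anatomy: no mediastinum, no pathology, no detector
physics, no inter-patient intensity calibration. A green end-to-end test
therefore establishes that the mathematics, gradients, optimisation and
sampling machinery are correct and reproducible — not that the model
reaches radiograph-quality synthesis, which in the source recipe required
GPU training on real data. The recipe's reported component losses
(reconstruction 0.869, diffusion 8e-4, latent 5.74e-5) depend on that
external data, unstated loss weights and multi-hour training, and are
deliberately not asserted anywhere in this package.

## Numerical choices

* Gradients are hand-derived (no autodiff exists in this stack) and checked
  against central finite differences at relative tolerance 1e-4.
* Zero-initialised residual-branch closers and score-net output projections
  make the score net predict exactly zero noise at step 0 — stable early
  training, and it gives the analytic zero-predictor expectation
  $\tfrac12(\gamma_{\max} - \gamma_{\min})\,d$ as a step-0 oracle.
* The Bernoulli NLL uses the softplus-logit form; ±Inf logits paired with
  binary targets yield exactly 0 loss.
* `transitionParams()` clamps tiny negative variances (floating-point
  cancellation at $s \approx t$) to 0.
* Degenerate inputs error early: times outside $[0,1]$, $s \ge t$
  posteriors, images smaller than 2×2 for the differential loss, empty
  datasets, negative loss weights.
* Time embeddings are sinusoidal with geometric frequencies $10^0 \dots
  10^4$ (the source names the embedding but not its form); the score net
  embeds the gamma value it conditions on.
* Weight decay applies to weight matrices only, never biases (standard
  AdamW practice), regression-tested via the parameter inventory.
* All stochastic entry points take explicit seeds and restore the caller's
  RNG state; training checkpoints carry the RNG state so resumed runs
  reproduce uninterrupted ones bit-exactly.

## Implementation notes specific to this stack

PNG input/output is a minimal built-in codec (8-bit grayscale write;
grayscale/RGB read with Rec. 601 luminance collapse) on top of R's zlib
bindings, cross-checked against Pillow in the tests — no R PNG package is
available in the target environment. Configs and manifests are JSON rather
than YAML for the same reason. Checkpoints are RDS archives of the flat
named parameter list plus optimizer state, step counter and RNG state.

## Known limitations

Dense networks on flattened pixels scale quadratically with pixel count, so
256×256 training is impractical on CPU (the `paper` preset exists for
completeness). No U-Net/attention backbone, no classifier-free guidance, no
DDIM-style deterministic sampler, no EMA, no mixed precision, no
distributed training. Class conditioning exists only as an optional
conditioning-vector hook (`condDim`), defaulting to unconditional.
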