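# VPDiffusion

Variance-preserving variational diffusion models (VDMs) for grayscale
medical images, in pure R.

## The problem

Generative models of radiographs are useful wherever real images are scarce
or restricted: teaching material, method prototyping, augmentation studies.
A variational diffusion model learns a generator by gradually noising images
and training networks to invert the corruption. This package implements the
full recipe — the closed-form Gaussian diffusion mathematics, the learnable
networks, the evidence-lower-bound objective, reverse-time sampling, and the
optimisation loop — for grayscale images such as chest X-rays, and ships a
seeded synthetic chest-phantom generator so the entire pipeline runs and is
tested end-to-end without any external dataset.

## The model

The forward process maps an image (or its encoded latent) `x` to noisy
latents `z_t`, `t ∈ [0, 1]`, through a log-signal-to-noise schedule γ(t):

    sigma_t^2 = logistic(gamma(t)),  alpha_t^2 = 1 - sigma_t^2
    q(z_t | x) = N(alpha_t x, sigma_t^2 I),   SNR(t) = alpha_t^2 / sigma_t^2 = exp(-gamma(t))

so the process is variance-preserving and the SNR is strictly decreasing
whenever γ is increasing. Transitions `q(z_t | z_s)` and Bayes posteriors
`q(z_s | z_t, x)` are Gaussian in closed form. γ(t) is either linear between
`gammaMin = 0.1` and `gammaMax = 1.0` (the package default, tabulated on a
50 × 1000 grid) or a learned monotonic network that is nondecreasing for
*every* parameter setting.

Learnable components: a dense-ResNet encoder to a 64-dimensional latent
space, a decoder with a mean-field Bernoulli observational model (per-pixel
logits), and a FiLM-conditioned score network (embedding dimension 128,
10 residual layers, swish activations) that predicts the injected noise
ε from `(z_t, γ(t))`. Training minimises

    L = w_rec * reconstruction + w_dif * diffusion + w_lat * latent + w_grad * differential

where reconstruction is the Bernoulli negative log-likelihood, the
diffusion term is the schedule-weighted expected squared noise-prediction
error `0.5 E[γ'(t) ||ε - ε̂||²]` (estimated with antithetic, stratified
times), the latent term is `KL(q(z_1|x) || N(0, I))`, and the differential
term penalises mismatched finite-difference image gradients. Optimisation
is AdamW (lr 8e-4, b1 0.9, b2 0.99, eps 1e-8, weight decay 1e-4) under a
linear 250-step warmup and cosine decay to 1e-5. Generation runs the
reverse chain from `z_1 ~ N(0, I)` through the closed-form posterior with
the predicted noise substituted. There is no autodiff dependency: analytic
backpropagation is implemented alongside every forward pass and verified
against finite differences in the tests.

## Worked example

```r
library(VPDiffusion)

phantoms <- generatePhantoms(phantomConfig(imageSize = 16L, nImages = 200L, seed = 0L))
run <- trainVDM(phantoms,
                modelConfig(imageSize = 16L),
                trainConfig(totalSteps = 500L, batchSize = 16L, seed = 0L))
tail(run$history, 2)
#>    step reconstruction diffusion   latent differential    total          lr
#> 10  450       148.9850   7.75866 1.441841   0.01068813 158.1962 1.95852e-05
#> 11  500       151.8839   7.35096 1.437564   0.01024995 160.6827 8.00000e-09
```

Starting from 229.2 nats per image at step 0, five hundred AdamW steps cut
the weighted total to ~160 nats (about 30%): the reconstruction term
(Bernoulli NLL summed over the 256 pixels) dominates, the diffusion term
falls as the score network learns the noise, and the latent KL stays small
because the encoder keeps its outputs close to the prior scale. Sampling
and evaluation then take one call each:

```r
imgs <- ancestralSample(run$params, run$modelCfg,
                        samplerConfig(nSteps = 5L, seed = 1L), nImages = 4L)
saveImages(imgs, "samples")
totalLoss(phantoms, run$params, run$modelCfg, seed = 1L)
```

The same pipeline is scriptable from a shell via
`inst/cli/vpdiffusion.R` (`train` / `sample` / `eval` subcommands, JSON
configs, `fast` and `paper` presets; exit codes 0/2/3 for
success/config/data errors).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it generates seeded phantoms, trains for 500 steps with the reference
optimiser recipe at 16 × 16, samples images by reverse diffusion, evaluates
the loss decomposition on a held-out phantom batch, and writes the JSON
result manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
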