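# Reverse-time ancestral generation. Each reverse step plugs the predicted
# noise into the closed-form Bayes posterior q(z_s | z_t, xhat):
#   xhat = (z_t - sigma_t epsHat) / alpha_t
#   z_s  = posterior mean(z_t, xhat) + temperature * sqrt(posterior var) * noise

#' One reverse (denoising) step
#'
#' Forms the implied clean tensor \code{xhat = (z_t - sigma_t epsHat) /
#' alpha_t} and draws \code{z_s} from the closed-form posterior
#' \code{q(z_s | z_t, xhat)} with the reverse-noise standard deviation
#' scaled by \code{temperature} (0 gives the deterministic posterior-mean
#' map).
#'
#' @param zt latent tensor at time \code{t}.
#' @param s,t times with \code{0 <= s < t <= 1}.
#' @param epsHat predicted noise, same shape as \code{zt}.
#' @param noise standard-normal tensor, same shape as \code{zt}.
#' @param schedule a [GammaSchedule-class].
#' @param temperature nonnegative multiplier on the reverse noise.
#' @return latent tensor at time \code{s}, same shape as \code{zt}.
#' @export
reverseStep <- function(zt, s, t, epsHat, noise, schedule,
                        temperature = 1.0) {
  .checkTimes(c(s, t))
  if (s >= t) stop("reverse step requires s < t", call. = FALSE)
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  pc <- .posteriorCoef(s, t, schedule)
  xhat <- (zt - pc$sigmaT * epsHat) / pc$alphaT
  pc$coefZ * zt + pc$coefX * xhat + temperature * sqrt(pc$var) * noise
}

#' Ancestral sampling in a generic latent space
#'
#' Starts from \code{z_1 ~ N(0, I)} (or a supplied initial draw) and applies
#' \code{nSteps} reverse steps on the uniform time grid \code{i/nSteps}.
#' This is the sampling engine behind [ancestralSample()]; exposing it over
#' an arbitrary noise predictor makes the sampler testable against
#' closed-form optimal denoisers.
#'
#' @param noisePredictor \code{function(z, gamma, t)} returning predicted
#'   noise for a (n, dim) matrix \code{z} and scalar \code{gamma}, \code{t}.
#' @param schedule a [GammaSchedule-class].
#' @param nSteps reverse step count T.
#' @param n number of chains (rows).
#' @param dim latent dimension (columns).
#' @param seed optional RNG seed.
#' @param temperature reverse-noise multiplier.
#' @param init optional (n, dim) matrix of initial latents at \code{t = 1};
#'   default standard normal.
#' @return (n, dim) matrix of latents at \code{t = 0}.
#' @export
sampleLatents <- function(noisePredictor, schedule, nSteps, n, dim,
                          seed = NULL, temperature = 1.0, init = NULL) {
  if (!.isCount(nSteps)) stop("nSteps must be an integer >= 1", call. = FALSE)
  run <- function() {
    z <- if (is.null(init)) matrix(rnorm(n * dim), n, dim) else init
    for (i in seq(nSteps, 1L)) {
      s <- (i - 1) / nSteps
      t <- i / nSteps
      epsHat <- noisePredictor(z, gammaAt(schedule, t), t)
      noise <- if (temperature > 0) matrix(rnorm(n * dim), n, dim) else 0
      z <- reverseStep(z, s, t, epsHat, noise, schedule, temperature)
    }
    z
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Generate images by reverse diffusion
#'
#' Draws latents by ancestral sampling with the score network as noise
#' predictor, then decodes \code{z_0} and returns the Bernoulli mean
#' \code{plogis(logits)} as the grayscale image (set
#' \code{pixelSample = TRUE} to draw binary pixels from the Bernoulli
#' observational model instead). Deterministic given the sampler seed.
#'
#' @param params parameters from [initModelParams()] or a trained checkpoint.
#' @param config the matching [ModelConfig-class].
#' @param sampler a [SamplerConfig-class] (steps, seed, temperature).
#' @param schedule a [GammaSchedule-class].
#' @param nImages number of images to generate.
#' @param conditioning optional extra conditioning passed to [scoreNet()].
#' @param pixelSample draw binary pixels instead of returning the mean.
#' @return an [ImageBatch-class] with values in \code{(0, 1)} (or
#'   \code{{0, 1}} when \code{pixelSample}).
#' @export
ancestralSample <- function(params, config, sampler = samplerConfig(),
                            schedule = linearGammaSchedule(), nImages = 1L,
                            conditioning = NULL, pixelSample = FALSE) {
  stopifnot(is(config, "ModelConfig"), is(sampler, "SamplerConfig"))
  D <- config@latentDim
  .withSeed(sampler@seed, {
    pred <- function(z, g, t) scoreNet(z, g, params, config, conditioning)
    z0 <- sampleLatents(pred, schedule, sampler@nSteps, nImages, D,
                        temperature = sampler@temperature)
    probs <- plogis(.decFwd(z0, params, config)$out)
    img <- if (pixelSample) {
      matrix(as.numeric(runif(length(probs)) < probs), nrow(probs))
    } else probs
    ImageBatch(array(img, c(nImages, config@imageSize, config@imageSize)),
               sprintf("sampled-T%d-seed%d-%03d", sampler@nSteps,
                       sampler@seed, seq_len(nImages)))
  })
}
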