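# S4 containers for the diffusion model: schedules, Gaussian coefficient
# bundles, architecture/optimisation configs, image batches, loss breakdowns.

.isCount <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 1

# ---------------------------------------------------------------------------
# Noise schedules

#' Noise schedules on the log-SNR (gamma) scale
#'
#' A schedule maps diffusion time \code{t} in \code{[0, 1]} to gamma, the
#' log-noise parameter of the variance-preserving process:
#' \code{sigma_t^2 = plogis(gamma(t))}, \code{alpha_t^2 = plogis(-gamma(t))},
#' so the signal-to-noise ratio is \code{exp(-gamma(t))} and is strictly
#' decreasing whenever gamma is strictly increasing.
#'
#' \code{LinearGammaSchedule} interpolates linearly between \code{gammaMin}
#' at \code{t = 0} and \code{gammaMax} at \code{t = 1}.
#' \code{LearnedGammaSchedule} wraps a monotonic neural network
#' (nonnegative-weight dense layer with sigmoid units plus a strictly positive
#' linear term), affinely rescaled so the endpoints hit \code{gammaMin} and
#' \code{gammaMax} exactly for every parameter setting.
#'
#' @slot gammaMin gamma at \code{t = 0} (default 0.1).
#' @slot gammaMax gamma at \code{t = 1} (default 1.0); must exceed
#'   \code{gammaMin}.
#' @slot nGrid number of linearly spaced steps of the tabulation grid
#'   (default 50).
#' @slot nSubsteps subdivisions per grid step for fine evaluation
#'   (default 1000).
#' @slot weights (learned variant) raw, unconstrained parameters; monotonicity
#'   is structural via a softplus reparameterisation, not a property of the
#'   fitted values.
#' @slot hidden (learned variant) number of sigmoid units.
#' @seealso [gammaAt()], [gammaPrimeAt()], [gammaGrid()]
#' @aliases LinearGammaSchedule-class LearnedGammaSchedule-class
#' @export
setClass("GammaSchedule",
  representation("VIRTUAL",
    gammaMin = "numeric", gammaMax = "numeric",
    nGrid = "integer", nSubsteps = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@gammaMin) || !is.finite(object@gammaMax))
      msg <- c(msg, "gammaMin and gammaMax must be finite")
    else if (object@gammaMax <= object@gammaMin)
      msg <- c(msg, "gammaMax must be strictly greater than gammaMin")
    if (!.isCount(object@nGrid) || object@nGrid < 2L)
      msg <- c(msg, "nGrid must be an integer >= 2")
    if (!.isCount(object@nSubsteps))
      msg <- c(msg, "nSubsteps must be an integer >= 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname GammaSchedule-class
#' @export
setClass("LinearGammaSchedule", contains = "GammaSchedule")

#' @rdname GammaSchedule-class
#' @export
setClass("LearnedGammaSchedule",
  contains = "GammaSchedule",
  representation(weights = "list", hidden = "integer"),
  validity = function(object) {
    w <- object@weights
    need <- c("w0", "W1", "b1", "W2")
    if (!all(need %in% names(w)))
      return(sprintf("weights must contain %s", paste(need, collapse = ", ")))
    h <- object@hidden
    if (length(w$W1) != h || length(w$b1) != h || length(w$W2) != h)
      return("W1, b1, W2 must each have length `hidden`")
    if (length(w$w0) != 1L) return("w0 must be a scalar")
    TRUE
  })

# ---------------------------------------------------------------------------
# Gaussian coefficient bundles

#' Closed-form Gaussian coefficients of the forward process
#'
#' \code{MarginalParams} holds the coefficients of the marginal
#' \code{q(z_t | x) = N(alpha_t x, sigma_t^2 I)}; variance preservation
#' (\code{alpha_t^2 + sigma_t^2 = 1}) is enforced by the validity method to
#' within 1e-12. \code{TransitionParams} holds \code{q(z_t | z_s)} with
#' \code{alphaTS = alpha_t / alpha_s} and
#' \code{sigma2TS = sigma_t^2 - alphaTS^2 sigma_s^2 >= 0}.
#' \code{PosteriorParams} holds the Bayes posterior
#' \code{q(z_s | z_t, x) = N(mean, variance I)}; conditioning can only shrink
#' variance, so \code{variance <= sigma_s^2}.
#'
#' @slot alpha,sigma marginal signal coefficient and noise standard deviation.
#' @slot alphaTS,sigma2TS transition signal coefficient and variance.
#' @slot mean posterior mean, same shape as the latent.
#' @slot variance posterior variance (scalar, shared across dimensions).
#' @aliases TransitionParams-class PosteriorParams-class
#' @seealso [marginalParams()], [transitionParams()], [posteriorParams()]
#' @export
setClass("MarginalParams",
  representation(alpha = "numeric", sigma = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != length(object@sigma))
      return("alpha and sigma must have equal length")
    if (any(object@alpha <= 0) || any(object@sigma < 0))
      return("alpha must be positive, sigma nonnegative")
    dev <- abs(object@alpha^2 + object@sigma^2 - 1)
    if (any(dev > 1e-12))
      return(sprintf("variance preservation violated: |alpha^2+sigma^2-1| = %.3g",
                     max(dev)))
    TRUE
  })

#' @rdname MarginalParams-class
#' @export
setClass("TransitionParams",
  representation(alphaTS = "numeric", sigma2TS = "numeric"),
  validity = function(object) {
    if (any(object@sigma2TS < -1e-12))
      return("transition variance must be nonnegative")
    TRUE
  })

#' @rdname MarginalParams-class
#' @export
setClass("PosteriorParams",
  representation(mean = "ANY", variance = "numeric"),
  validity = function(object) {
    if (length(object@variance) != 1L || object@variance < -1e-12)
      return("variance must be a nonnegative scalar")
    TRUE
  })

# ---------------------------------------------------------------------------
# Configuration objects

#' Architecture configuration
#'
#' Dimensions of the dense-ResNet encoder, Bernoulli decoder and
#' FiLM-conditioned score network. Defaults follow the reference recipe:
#' latent dimension 64, six residual blocks in encoder and decoder, score
#' embedding dimension 128 with 10 residual layers, 256x256 images. Networks
#' operate on flattened pixel vectors, so small \code{imageSize} values
#' (16 or 32) are the practical choice for CPU-scale work.
#'
#' @slot latentDim dimension of the diffusion latent space (default 64).
#' @slot encoderBlocks,decoderBlocks residual block counts (default 6 each).
#' @slot scoreEmbeddingDim sinusoidal time-embedding width and conditioning
#'   width of the score network (default 128, must be even).
#' @slot scoreLayers residual layers in the score network (default 10).
#' @slot imageSize pixels per side (default 256, must be even).
#' @slot condDim optional extra conditioning-vector length (default 0,
#'   unconditional).
#' @seealso [modelConfig()], [initModelParams()]
#' @export
setClass("ModelConfig",
  representation(latentDim = "integer", encoderBlocks = "integer",
    decoderBlocks = "integer", scoreEmbeddingDim = "integer",
    scoreLayers = "integer", imageSize = "integer", condDim = "integer"),
  validity = function(object) {
    counts <- c(latentDim = object@latentDim,
                encoderBlocks = object@encoderBlocks,
                decoderBlocks = object@decoderBlocks,
                scoreEmbeddingDim = object@scoreEmbeddingDim,
                scoreLayers = object@scoreLayers,
                imageSize = object@imageSize)
    bad <- names(counts)[!vapply(counts, .isCount, logical(1))]
    if (length(bad))
      return(sprintf("positive integer required for: %s",
                     paste(bad, collapse = ", ")))
    if (object@imageSize %% 2L != 0L) return("imageSize must be even")
    if (object@scoreEmbeddingDim %% 2L != 0L)
      return("scoreEmbeddingDim must be even")
    if (object@condDim < 0L) return("condDim must be >= 0")
    TRUE
  })

#' Optimisation configuration
#'
#' AdamW with a linear warmup and cosine decay, following the reference
#' recipe: base learning rate 8e-4, warmup over 250 steps from a factor of 0
#' to 1, cosine decay from 1 to 1e-5 over \code{totalSteps}, b1 = 0.9,
#' b2 = 0.99, eps = 1e-8, weight decay 1e-4, batch size 64.
#'
#' @slot baseLR peak learning rate.
#' @slot warmupSteps linear warmup length in steps.
#' @slot totalSteps total optimisation steps (cosine horizon).
#' @slot finalDecay terminal multiplier of the cosine decay.
#' @slot b1,b2 AdamW moment coefficients.
#' @slot eps AdamW numerical epsilon.
#' @slot weightDecay decoupled weight-decay coefficient (matrices only;
#'   biases are never decayed).
#' @slot batchSize images per update.
#' @slot seed integer RNG seed for batching and noise draws.
#' @seealso [trainConfig()], [trainVDM()], [lrAt()]
#' @export
setClass("TrainConfig",
  representation(baseLR = "numeric", warmupSteps = "integer",
    totalSteps = "integer", finalDecay = "numeric", b1 = "numeric",
    b2 = "numeric", eps = "numeric", weightDecay = "numeric",
    batchSize = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@b1 <= 0 || object@b1 >= 1 || object@b2 <= 0 || object@b2 >= 1)
      msg <- c(msg, "b1 and b2 must lie strictly in (0, 1)")
    if (object@warmupSteps > object@totalSteps)
      msg <- c(msg, "warmupSteps must not exceed totalSteps")
    if (object@baseLR < 0)
      msg <- c(msg, "baseLR must be nonnegative (0 freezes the parameters)")
    if (object@eps <= 0 || object@finalDecay <= 0)
      msg <- c(msg, "eps and finalDecay must be positive")
    if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
    if (!.isCount(object@batchSize)) msg <- c(msg, "batchSize must be >= 1")
    if (!.isCount(object@totalSteps)) msg <- c(msg, "totalSteps must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Ancestral sampler configuration
#'
#' @slot nSteps number of reverse steps T. The architecture summary of the
#'   reference recipe uses 5 (the `fast` preset); its image generation used
#'   20,000 (the `paper` preset).
#' @slot seed RNG seed.
#' @slot temperature multiplier on the reverse-noise standard deviation;
#'   0 gives the deterministic posterior-mean trajectory.
#' @seealso [samplerConfig()], [ancestralSample()]
#' @export
setClass("SamplerConfig",
  representation(nSteps = "integer", seed = "integer",
                 temperature = "numeric"),
  validity = function(object) {
    if (!.isCount(object@nSteps)) return("nSteps must be an integer >= 1")
    if (object@temperature < 0) return("temperature must be >= 0")
    TRUE
  })

#' Synthetic chest-phantom configuration
#'
#' @slot imageSize pixels per side.
#' @slot nImages number of phantoms (default 1341, the size of the chest
#'   X-ray training subset the phantoms stand in for).
#' @slot seed RNG seed; generation is bit-reproducible per seed.
#' @slot ribCount darker rib-like bands crossing the lung fields (default 7).
#' @slot noiseSD additive Gaussian noise, intensity units (default 0.02).
#' @slot lungEllipticity relative jitter range of lung position/axes
#'   (default 0.08).
#' @seealso [phantomConfig()], [generatePhantoms()]
#' @export
setClass("PhantomConfig",
  representation(imageSize = "integer", nImages = "integer", seed = "integer",
    ribCount = "integer", noiseSD = "numeric", lungEllipticity = "numeric"),
  validity = function(object) {
    if (!.isCount(object@imageSize) || !.isCount(object@nImages))
      return("imageSize and nImages must be positive integers")
    if (object@ribCount < 0L) return("ribCount must be >= 0")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    if (object@lungEllipticity < 0 || object@lungEllipticity >= 1)
      return("lungEllipticity must lie in [0, 1)")
    TRUE
  })

# ---------------------------------------------------------------------------
# Data containers

#' A batch of grayscale images
#'
#' Intensities are stored as an (n, H, W) array with values in \code{[0, 1]};
#' every image carries a provenance tag (filename or generator label).
#'
#' @slot intensities numeric array (n, H, W) in \code{[0, 1]}.
#' @slot sourceTags character vector, one tag per image.
#' @seealso [generatePhantoms()], [loadImages()], [saveImages()]
#' @export
setClass("ImageBatch",
  representation(intensities = "array", sourceTags = "character"),
  validity = function(object) {
    d <- dim(object@intensities)
    if (length(d) != 3L) return("intensities must be an (n, H, W) array")
    if (length(object@sourceTags) != d[1L])
      return("sourceTags must have one entry per image")
    rng <- range(object@intensities)
    if (!all(is.finite(rng))) return("intensities must be finite")
    if (rng[1L] < 0 || rng[2L] > 1)
      return("intensities must lie in [0, 1]")
    TRUE
  })

#' Per-term loss decomposition
#'
#' Evidence-lower-bound terms for a batch, in nats per image (sums over
#' pixels or latent dimensions, averaged over the batch), plus the
#' image-gradient differential penalty. \code{total} is the weighted sum;
#' diffusion and latent terms are KL divergences and hence nonnegative.
#'
#' @slot reconstruction Bernoulli negative log-likelihood.
#' @slot diffusion schedule-weighted expected squared noise-prediction error.
#' @slot latent KL from the fully noised marginal to the standard-normal prior.
#' @slot differential mean squared finite-difference gradient mismatch.
#' @slot weights named nonnegative weights (reconstruction, diffusion,
#'   latent, differential).
#' @slot total weighted sum of the four terms.
#' @seealso [totalLoss()]
#' @export
setClass("LossBreakdown",
  representation(reconstruction = "numeric", diffusion = "numeric",
    latent = "numeric", differential = "numeric", weights = "numeric",
    total = "numeric"),
  validity = function(object) {
    terms <- c(reconstruction = object@reconstruction,
               diffusion = object@diffusion, latent = object@latent,
               differential = object@differential)
    if (any(!is.finite(terms))) return("loss terms must be finite")
    if (object@diffusion < 0 || object@latent < 0)
      return("diffusion and latent terms are KL divergences and must be >= 0")
    if (object@differential < 0) return("differential term must be >= 0")
    w <- object@weights
    if (!identical(sort(names(w)), sort(names(terms))))
      return("weights must be named reconstruction, diffusion, latent, differential")
    if (any(w < 0)) return("weights must be nonnegative")
    tot <- sum(w[names(terms)] * terms)
    if (abs(object@total - tot) > 1e-8 * max(1, abs(tot)))
      return("total must equal the weighted sum of the terms")
    TRUE
  })

# ---------------------------------------------------------------------------
# Constructors

#' @describeIn GammaSchedule-class linear schedule constructor.
#' @param gammaMin,gammaMax,nGrid,nSubsteps see slots.
#' @export
linearGammaSchedule <- function(gammaMin = 0.1, gammaMax = 1.0,
                                nGrid = 50L, nSubsteps = 1000L) {
  new("LinearGammaSchedule", gammaMin = as.numeric(gammaMin),
      gammaMax = as.numeric(gammaMax), nGrid = as.integer(nGrid),
      nSubsteps = as.integer(nSubsteps))
}

#' @describeIn GammaSchedule-class learned monotonic schedule constructor;
#'   raw weights are drawn from N(0, 1) under \code{seed} unless supplied.
#' @param hidden sigmoid unit count of the monotonic network.
#' @param seed RNG seed for the random raw weights.
#' @param weights optional list with elements \code{w0}, \code{W1},
#'   \code{b1}, \code{W2} (raw, unconstrained).
#' @export
learnedGammaSchedule <- function(gammaMin = 0.1, gammaMax = 1.0,
                                 hidden = 10L, seed = 1L, weights = NULL,
                                 nGrid = 50L, nSubsteps = 1000L) {
  hidden <- as.integer(hidden)
  if (is.null(weights)) {
    weights <- .withSeed(seed, list(w0 = rnorm(1L), W1 = rnorm(hidden),
                                    b1 = rnorm(hidden), W2 = rnorm(hidden)))
  }
  new("LearnedGammaSchedule", gammaMin = as.numeric(gammaMin),
      gammaMax = as.numeric(gammaMax), nGrid = as.integer(nGrid),
      nSubsteps = as.integer(nSubsteps), weights = weights, hidden = hidden)
}

#' Construct a [ModelConfig-class]
#'
#' @param latentDim,encoderBlocks,decoderBlocks,scoreEmbeddingDim,scoreLayers,imageSize,condDim
#'   see the class slots; defaults are the reference recipe's values.
#' @return a validated \code{ModelConfig}.
#' @export
modelConfig <- function(latentDim = 64L, encoderBlocks = 6L,
                        decoderBlocks = 6L, scoreEmbeddingDim = 128L,
                        scoreLayers = 10L, imageSize = 256L, condDim = 0L) {
  new("ModelConfig", latentDim = as.integer(latentDim),
      encoderBlocks = as.integer(encoderBlocks),
      decoderBlocks = as.integer(decoderBlocks),
      scoreEmbeddingDim = as.integer(scoreEmbeddingDim),
      scoreLayers = as.integer(scoreLayers),
      imageSize = as.integer(imageSize), condDim = as.integer(condDim))
}

#' Construct a [TrainConfig-class]
#'
#' @param baseLR,warmupSteps,totalSteps,finalDecay,b1,b2,eps,weightDecay,batchSize,seed
#'   see the class slots; defaults are the reference optimisation recipe.
#' @return a validated \code{TrainConfig}.
#' @export
trainConfig <- function(baseLR = 8e-4, warmupSteps = 250L,
                        totalSteps = 20000L, finalDecay = 1e-5, b1 = 0.9,
                        b2 = 0.99, eps = 1e-8, weightDecay = 1e-4,
                        batchSize = 64L, seed = 0L) {
  new("TrainConfig", baseLR = as.numeric(baseLR),
      warmupSteps = as.integer(warmupSteps),
      totalSteps = as.integer(totalSteps),
      finalDecay = as.numeric(finalDecay), b1 = as.numeric(b1),
      b2 = as.numeric(b2), eps = as.numeric(eps),
      weightDecay = as.numeric(weightDecay),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Construct a [SamplerConfig-class]
#'
#' @param nSteps,seed,temperature see the class slots.
#' @export
samplerConfig <- function(nSteps = 5L, seed = 0L, temperature = 1.0) {
  new("SamplerConfig", nSteps = as.integer(nSteps), seed = as.integer(seed),
      temperature = as.numeric(temperature))
}

#' Construct a [PhantomConfig-class]
#'
#' @param imageSize,nImages,seed,ribCount,noiseSD,lungEllipticity see the
#'   class slots.
#' @export
phantomConfig <- function(imageSize = 256L, nImages = 1341L, seed = 0L,
                          ribCount = 7L, noiseSD = 0.02,
                          lungEllipticity = 0.08) {
  new("PhantomConfig", imageSize = as.integer(imageSize),
      nImages = as.integer(nImages), seed = as.integer(seed),
      ribCount = as.integer(ribCount), noiseSD = as.numeric(noiseSD),
      lungEllipticity = as.numeric(lungEllipticity))
}

#' @describeIn ImageBatch-class constructor.
#' @param intensities (n, H, W) array in \code{[0, 1]}.
#' @param sourceTags per-image provenance strings (recycled from a scalar).
#' @export
ImageBatch <- function(intensities, sourceTags = "unknown") {
  if (is.matrix(intensities))
    intensities <- array(intensities, c(1L, dim(intensities)))
  n <- dim(intensities)[1L]
  if (length(sourceTags) == 1L) sourceTags <- rep(sourceTags, n)
  new("ImageBatch", intensities = intensities,
      sourceTags = as.character(sourceTags))
}

.lossBreakdown <- function(reconstruction, diffusion, latent, differential,
                           weights) {
  terms <- c(reconstruction = reconstruction, diffusion = diffusion,
             latent = latent, differential = differential)
  new("LossBreakdown", reconstruction = reconstruction, diffusion = diffusion,
      latent = latent, differential = differential, weights = weights,
      total = sum(weights[names(terms)] * terms))
}

# ---------------------------------------------------------------------------
# Accessors and show methods

#' @rdname ImageBatch-class
setMethod("intensities", "ImageBatch", function(x) x@intensities)

#' @rdname ImageBatch-class
setMethod("sourceTags", "ImageBatch", function(x) x@sourceTags)

#' @rdname ImageBatch-class
setMethod("nImages", "ImageBatch", function(x) dim(x@intensities)[1L])

#' @rdname ImageBatch-class
#' @param i index vector.
#' @param j,...,drop ignored (images are always kept 3-dimensional).
setMethod("[", "ImageBatch", function(x, i, j, ..., drop = FALSE) {
  ImageBatch(x@intensities[i, , , drop = FALSE], x@sourceTags[i])
})

setMethod("show", "ImageBatch", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ImageBatch: %d image(s), %dx%d, intensity range [%.3f, %.3f]\n",
              d[1L], d[2L], d[3L], min(object@intensities),
              max(object@intensities)))
  cat(sprintf("  tags: %s%s\n",
              paste(utils::head(object@sourceTags, 3L), collapse = ", "),
              if (d[1L] > 3L) ", ..." else ""))
})

setMethod("show", "LinearGammaSchedule", function(object) {
  cat(sprintf(
    "LinearGammaSchedule: gamma %.4g -> %.4g (SNR %.4g -> %.4g), grid %dx%d\n",
    object@gammaMin, object@gammaMax, exp(-object@gammaMin),
    exp(-object@gammaMax), object@nGrid, object@nSubsteps))
})

setMethod("show", "LearnedGammaSchedule", function(object) {
  cat(sprintf(
    "LearnedGammaSchedule: gamma %.4g -> %.4g, %d monotone units, grid %dx%d\n",
    object@gammaMin, object@gammaMax, object@hidden, object@nGrid,
    object@nSubsteps))
})

#' @rdname LossBreakdown-class
setMethod("lossTerms", "LossBreakdown", function(object) {
  c(reconstruction = object@reconstruction, diffusion = object@diffusion,
    latent = object@latent, differential = object@differential)
})

#' @rdname LossBreakdown-class
setMethod("lossWeights", "LossBreakdown", function(object) object@weights)

#' @rdname LossBreakdown-class
setMethod("lossTotal", "LossBreakdown", function(object) object@total)

setMethod("show", "LossBreakdown", function(object) {
  t <- lossTerms(object)
  w <- object@weights[names(t)]
  cat("LossBreakdown (nats per image):\n")
  for (nm in names(t))
    cat(sprintf("  %-14s %12.6g  (weight %g)\n", nm, t[[nm]], w[[nm]]))
  cat(sprintf("  %-14s %12.6g\n", "total", object@total))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0(
    "ModelConfig: %dx%d images, latent %d, enc/dec blocks %d/%d, ",
    "score %d layers (embed %d), cond %d\n"),
    object@imageSize, object@imageSize, object@latentDim,
    object@encoderBlocks, object@decoderBlocks, object@scoreLayers,
    object@scoreEmbeddingDim, object@condDim))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0(
    "TrainConfig: lr %g (warmup %d, cosine to %g over %d), ",
    "b1 %g b2 %g eps %g wd %g, batch %d, seed %d\n"),
    object@baseLR, object@warmupSteps, object@finalDecay, object@totalSteps,
    object@b1, object@b2, object@eps, object@weightDecay, object@batchSize,
    object@seed))
})
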