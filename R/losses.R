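# The training objective: Bernoulli reconstruction, discrete- and
# continuous-time diffusion losses, latent (prior) KL, image-gradient
# differential loss, antithetic time sampling, and the assembled total loss
# with analytic gradients for the optimiser.
#
# Reporting convention: nats per image (sums over pixels / latent
# dimensions), averaged over the batch. The differential term is a mean over
# interior pixels.

# stable elementwise Bernoulli NLL from logits: softplus(l) - x * l
.bceFromLogits <- function(x, logits) {
  .softplus(logits) - x * logits
}

#' Bernoulli reconstruction loss
#'
#' Negative log-likelihood of intensities in \code{[0, 1]} under the
#' decoder's mean-field Bernoulli model, summed over pixels and (for batched
#' input) averaged over images. Computed in a numerically stable logit form
#' \code{softplus(l) - x l}, which never evaluates \code{log(0)} even for
#' logits at +/-Inf.
#'
#' @param x intensities in \code{[0, 1]}; an [ImageBatch-class], an
#'   (n, S, S) array (first dimension = batch), or a vector/matrix (treated
#'   as a single instance).
#' @param logits decoder output, same shape as \code{x}.
#' @return nats per image.
#' @export
reconstructionLoss <- function(x, logits) {
  if (is(x, "ImageBatch")) x <- intensities(x)
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]", call. = FALSE)
  dx <- dim(x)
  if (!identical(dx, dim(logits)) || length(x) != length(logits))
    stop("x and logits must have the same shape", call. = FALSE)
  nll <- .bceFromLogits(x, logits)
  nll[x == 0 & logits == -Inf] <- 0   # perfect-certainty limit
  nll[x == 1 & logits == Inf] <- 0
  if (length(dx) == 3L) sum(nll) / dx[1L] else sum(nll)
}

#' Latent (prior) KL loss
#'
#' KL divergence from the fully noised marginal
#' \code{q(z_1 | x) = N(alpha_1 x, sigma_1^2 I)} to the standard-normal
#' prior: \code{0.5 * sum(alpha_1^2 x^2 + sigma_1^2 - 1 - log(sigma_1^2))}.
#' Nonnegative for any input; zero only when the marginal already equals the
#' prior.
#'
#' @param x a vector (one instance, summed), a matrix (rows are instances,
#'   averaged), or an (n, S, S) array / [ImageBatch-class] (averaged over
#'   images).
#' @param schedule a [GammaSchedule-class].
#' @return nats per instance.
#' @export
latentLoss <- function(x, schedule) {
  g1 <- gammaAt(schedule, 1)
  sigma2 <- plogis(g1)
  if (sigma2 <= 0) stop("sigma_1 = 0 makes the prior KL infinite",
                        call. = FALSE)
  alpha2 <- plogis(-g1)
  const <- sigma2 - 1 - log(sigma2)
  if (is(x, "ImageBatch")) x <- intensities(x)
  d <- dim(x)
  if (length(d) == 3L) {
    perDim <- length(x) / d[1L]
    0.5 * (alpha2 * sum(x^2) / d[1L] + perDim * const)
  } else if (is.matrix(x)) {
    0.5 * (alpha2 * sum(x^2) / nrow(x) + ncol(x) * const)
  } else {
    0.5 * (alpha2 * sum(x^2) + length(x) * const)
  }
}

#' Antithetic (stratified) time sampling
#'
#' Places exactly one time in each interval \code{[i/n, (i+1)/n)}:
#' \code{t_i = frac(u0 + i/n)}. Sharing a single uniform offset across the
#' batch reduces the variance of the Monte-Carlo diffusion-loss estimate.
#'
#' @param n number of times (>= 1).
#' @param u0 uniform offset in \code{[0, 1)}.
#' @return numeric vector of \code{n} times in \code{[0, 1)}.
#' @export
antitheticTimes <- function(n, u0) {
  if (!.isCount(n)) stop("n must be an integer >= 1", call. = FALSE)
  if (u0 < 0 || u0 >= 1) stop("u0 must lie in [0, 1)", call. = FALSE)
  (u0 + (seq_len(n) - 1) / n) %% 1
}

#' Discrete-time diffusion loss
#'
#' Monte-Carlo estimate of
#' \code{(T/2) E[expm1(gamma(t_i) - gamma(s_i)) ||eps - epsHat||^2]} with
#' \code{s_i = (i-1)/T}, \code{t_i = i/T} and \code{i} uniform over steps
#' (stratified). This equals the KL divergence between the T-step forward
#' and reverse joint distributions for any predictor measurable in
#' \code{z_t}; it is nonincreasing in \code{T} and converges to
#' [diffusionLossContinuous()] as \code{T} grows.
#'
#' @param x clean tensor (numeric vector), one instance.
#' @param noisePredictor \code{function(z, gamma, t)} returning predicted
#'   noise, same shape as \code{z}; called with a (draws, length(x)) matrix
#'   \code{z} and \code{gamma}, \code{t} either scalars (discrete loss) or
#'   one value per row (continuous loss).
#' @param T number of discretisation steps (>= 1).
#' @param schedule a [GammaSchedule-class].
#' @param nDraws Monte-Carlo draws; draws are spread over steps in
#'   stratified fashion.
#' @param seed optional RNG seed (caller's RNG state is preserved).
#' @return the loss estimate, with attributes \code{se} (standard error) and
#'   \code{nDraws}.
#' @export
diffusionLossDiscrete <- function(x, noisePredictor, T, schedule,
                                  nDraws = 10000L, seed = NULL) {
  if (!.isCount(T)) stop("T must be an integer >= 1", call. = FALSE)
  run <- function() {
    u0 <- runif(1L)
    steps <- pmin(floor(antitheticTimes(nDraws, u0) * T) + 1L, T)
    d <- length(x)
    terms <- numeric(nDraws)
    for (i in sort(unique(steps))) {
      idx <- which(steps == i)
      s <- (i - 1) / T; t <- i / T
      gs <- gammaAt(schedule, s); gt <- gammaAt(schedule, t)
      p <- .alphaSigma(gt)
      eps <- matrix(rnorm(length(idx) * d), length(idx), d)
      z <- matrix(x, length(idx), d, byrow = TRUE) * p$alpha + eps * p$sigma
      epsHat <- noisePredictor(z, gt, t)
      terms[idx] <- (T / 2) * expm1(gt - gs) * rowSums((eps - epsHat)^2)
    }
    est <- mean(terms)
    attr(est, "se") <- stats::sd(terms) / sqrt(nDraws)
    attr(est, "nDraws") <- nDraws
    est
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Continuous-time diffusion loss
#'
#' Monte-Carlo estimate of
#' \code{0.5 E[gamma'(t) ||eps - epsHat||^2]} over antithetic times and
#' fresh noise. For the linear schedule \code{gamma'(t)} is the constant
#' \code{gammaMax - gammaMin}.
#'
#' @inheritParams diffusionLossDiscrete
#' @param nTimes number of antithetic Monte-Carlo times (>= 1).
#' @return the loss estimate, with attributes \code{se} and \code{nDraws}.
#' @export
diffusionLossContinuous <- function(x, noisePredictor, schedule,
                                    nTimes = 10000L, seed = NULL) {
  if (!.isCount(nTimes)) stop("nTimes must be an integer >= 1", call. = FALSE)
  run <- function() {
    u0 <- runif(1L)
    tt <- antitheticTimes(nTimes, u0)
    d <- length(x)
    g <- gammaAt(schedule, tt)
    gp <- gammaPrimeAt(schedule, tt)
    p <- .alphaSigma(g)
    eps <- matrix(rnorm(nTimes * d), nTimes, d)
    z <- matrix(x, nTimes, d, byrow = TRUE) * p$alpha + eps * p$sigma
    epsHat <- noisePredictor(z, g, tt)
    terms <- 0.5 * gp * rowSums((eps - epsHat)^2)
    est <- mean(terms)
    attr(est, "se") <- stats::sd(terms) / sqrt(nTimes)
    attr(est, "nDraws") <- nTimes
    est
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

# forward differences on the (S-1)x(S-1) interior grid
.gradPair <- function(m) {
  H <- nrow(m); W <- ncol(m)
  list(h = m[-H, -1, drop = FALSE] - m[-H, -W, drop = FALSE],
       v = m[-1, -W, drop = FALSE] - m[-H, -W, drop = FALSE])
}

#' Image-gradient (differential) loss
#'
#' Mean over interior pixels of the squared mismatch of forward
#' finite-difference gradients:
#' \code{(D_h x - D_h xhat)^2 + (D_v x - D_v xhat)^2}, last row and column
#' excluded. Invariant under constant intensity shifts; penalises edge
#' disagreement between an image and its reconstruction.
#'
#' @param x,xhat matrices (one image) or (n, S, S) arrays /
#'   [ImageBatch-class] (averaged over images); at least 2x2.
#' @return mean squared gradient mismatch.
#' @export
differentialLoss <- function(x, xhat) {
  if (is(x, "ImageBatch")) x <- intensities(x)
  if (is(xhat, "ImageBatch")) xhat <- intensities(xhat)
  if (!identical(dim(x), dim(xhat)))
    stop("x and xhat must have the same shape", call. = FALSE)
  one <- function(a, b) {
    if (nrow(a) < 2L || ncol(a) < 2L)
      stop("images must be at least 2x2", call. = FALSE)
    ga <- .gradPair(a); gb <- .gradPair(b)
    mean((ga$h - gb$h)^2 + (ga$v - gb$v)^2)
  }
  d <- dim(x)
  if (length(d) == 3L) {
    mean(vapply(seq_len(d[1L]),
                function(b) one(x[b, , ], xhat[b, , ]), numeric(1)))
  } else one(as.matrix(x), as.matrix(xhat))
}

# adjoint of the differential loss wrt xhat, for one image matrix.
# loss = mean((Dh x - Dh xhat)^2 + (Dv x - Dv xhat)^2) over (S-1)^2 pixels
.differentialGrad <- function(x, xhat) {
  H <- nrow(x); W <- ncol(x)
  gx <- .gradPair(x); gh <- .gradPair(xhat)
  eh <- gh$h - gx$h
  ev <- gh$v - gx$v
  g <- matrix(0, H, W)
  # adjoint of Dh: -e at (i,j), +e at (i,j+1), rows 1..H-1
  g[-H, -W] <- g[-H, -W] - eh
  g[-H, -1] <- g[-H, -1] + eh
  # adjoint of Dv: -e at (i,j), +e at (i+1,j), cols 1..W-1
  g[-H, -W] <- g[-H, -W] - ev
  g[-1, -W] <- g[-1, -W] + ev
  2 * g / ((H - 1) * (W - 1))
}

.defaultLossWeights <- c(reconstruction = 1, diffusion = 1, latent = 1,
                         differential = 1)

.checkWeights <- function(weights) {
  w <- .defaultLossWeights
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(names(weights) %in% names(w)))
      stop("weights must be named among: ",
           paste(names(w), collapse = ", "), call. = FALSE)
    w[names(weights)] <- weights
  }
  if (any(w < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  w
}

# Full objective for one batch; optionally with analytic parameter gradients.
# x2d: (B, npix) matrix. Consumes the ambient RNG stream (one uniform offset,
# two standard-normal tensors).
.lossCore <- function(x2d, params, config, schedule, weights,
                      computeGrad = FALSE) {
  B <- nrow(x2d)
  S <- config@imageSize
  D <- config@latentDim
  G <- if (computeGrad) new.env(parent = emptyenv()) else NULL

  encF <- .encFwd(x2d, params, config)
  f <- encF$out
  dF <- if (computeGrad) matrix(0, B, D)

  # latent KL at t = 1
  g1 <- gammaAt(schedule, 1)
  s2 <- plogis(g1); a2 <- plogis(-g1)
  latent <- 0.5 * (a2 * sum(f^2) / B + D * (s2 - 1 - log(s2)))
  if (computeGrad) dF <- dF + weights[["latent"]] * a2 * f / B

  # reconstruction through z_0 ~ q(z_0 | x)
  g0 <- gammaAt(schedule, 0)
  p0 <- .alphaSigma(g0)
  eps0 <- matrix(rnorm(B * D), B, D)
  z0 <- p0$alpha * f + p0$sigma * eps0
  decF <- .decFwd(z0, params, config)
  logits <- decF$out
  P <- plogis(logits)
  recon <- sum(.bceFromLogits(x2d, logits)) / B
  dLogits <- if (computeGrad) weights[["reconstruction"]] * (P - x2d) / B

  # differential loss between x and the decoded mean image
  dXhat <- if (computeGrad) matrix(0, B, S * S)
  diffTerms <- numeric(B)
  for (b in seq_len(B)) {
    xm <- matrix(x2d[b, ], S, S)
    pm <- matrix(P[b, ], S, S)
    gx <- .gradPair(xm); gp <- .gradPair(pm)
    diffTerms[b] <- mean((gx$h - gp$h)^2 + (gx$v - gp$v)^2)
    if (computeGrad)
      dXhat[b, ] <- as.vector(.differentialGrad(xm, pm)) / B
  }
  differential <- mean(diffTerms)
  if (computeGrad)
    dLogits <- dLogits + weights[["differential"]] * dXhat * P * (1 - P)

  if (computeGrad) {
    dZ0 <- .decBwd(dLogits, decF, params, config, G)
    dF <- dF + p0$alpha * dZ0
  }

  # continuous-time diffusion loss with antithetic times, one per image
  u0 <- runif(1L)
  tt <- antitheticTimes(B, u0)
  gt <- gammaAt(schedule, tt)
  gp <- gammaPrimeAt(schedule, tt)
  pt <- .alphaSigma(gt)
  epsD <- matrix(rnorm(B * D), B, D)
  zt <- f * pt$alpha + epsD * pt$sigma
  scF <- .scoreFwd(zt, gt, NULL, params, config)
  resid <- scF$out - epsD
  diffusion <- sum(0.5 * gp * rowSums(resid^2)) / B
  if (computeGrad) {
    dEpsHat <- weights[["diffusion"]] * (gp * resid) / B
    dZt <- .scoreBwd(dEpsHat, scF, params, config, G)
    dF <- dF + dZt * pt$alpha
    .encBwd(dF, encF, params, config, G)
  }

  breakdown <- .lossBreakdown(recon, diffusion, latent, differential, weights)
  grads <- NULL
  if (computeGrad) {
    grads <- lapply(names(params), function(nm) {
      g <- G[[nm]]
      if (is.null(g)) params[[nm]] * 0 else g
    })
    names(grads) <- names(params)
  }
  list(breakdown = breakdown, grads = grads)
}

#' Total training loss for a batch
#'
#' Assembles the four objective terms — Bernoulli reconstruction through a
#' draw of \code{z_0}, continuous-time diffusion loss with antithetic times
#' (one per image), the latent prior KL of the encoded batch, and the
#' image-gradient differential loss between each image and its decoded mean
#' — into a [LossBreakdown-class] whose total is the weighted sum.
#'
#' @param x an [ImageBatch-class] or (n, S, S) array in \code{[0, 1]}.
#' @param params parameters from [initModelParams()].
#' @param config the matching [ModelConfig-class].
#' @param schedule a [GammaSchedule-class].
#' @param weights named nonnegative weights; any subset of
#'   \code{reconstruction}, \code{diffusion}, \code{latent},
#'   \code{differential} (default all 1).
#' @param seed optional RNG seed; with a fixed seed the breakdown is
#'   bit-reproducible.
#' @return a [LossBreakdown-class].
#' @export
totalLoss <- function(x, params, config, schedule = linearGammaSchedule(),
                      weights = NULL, seed = NULL) {
  w <- .checkWeights(weights)
  x2d <- .asImageMatrix(x, config)
  run <- function() .lossCore(x2d, params, config, schedule, w)$breakdown
  if (is.null(seed)) run() else .withSeed(seed, run())
}
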