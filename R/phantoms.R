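# Seeded synthetic chest phantoms: a smooth vertical background gradient,
# two bright elliptical lung fields with jittered position/shape, darker
# rib-like sinusoidal bands crossing the lungs, and additive Gaussian noise.
# A statistical stand-in for frontal chest radiographs; not anatomy.

.smoothMask <- function(r, edge = 0.05) plogis((1 - r) / edge)

# one phantom; draws a fixed number of RNG values so images are independent
# of each other only through the stream order
.onePhantom <- function(S, cfg) {
  gx <- matrix(rep(seq(0, 1, length.out = S), each = S), S, S)  # column coord
  gy <- matrix(rep(seq(0, 1, length.out = S), times = S), S, S) # row coord
  jit <- cfg@lungEllipticity

  b0 <- 0.10 + 0.04 * runif(1L)
  slope <- 0.20 + 0.10 * runif(1L)
  img <- b0 + slope * gy

  cy <- 0.46 + jit * (runif(1L) - 0.5)
  amp <- 0.33 + 0.06 * runif(1L)
  lungW <- matrix(0, S, S)
  mask <- matrix(FALSE, S, S)
  for (cx in c(0.32, 0.68)) {
    cxj <- cx + jit * 0.5 * (runif(1L) - 0.5)
    rx <- 0.145 * (1 + jit * (runif(1L) - 0.5))
    ry <- 0.27 * (1 + jit * (runif(1L) - 0.5))
    r <- sqrt(((gx - cxj) / rx)^2 + ((gy - cy) / ry)^2)
    lungW <- pmax(lungW, .smoothMask(r))
    mask <- mask | (r < 1)
  }
  img <- img + amp * lungW

  if (cfg@ribCount > 0L) {
    ry0 <- cy - 0.27
    spacing <- 2 * 0.27 / cfg@ribCount
    curve <- 0.06 + 0.03 * runif(1L)
    bw <- 0.010 + 0.004 * runif(1L)
    phase <- runif(1L) * spacing * 0.3
    for (k in seq_len(cfg@ribCount)) {
      yk <- ry0 + (k - 0.5) * spacing + phase
      p <- gy - yk - curve * ((gx - 0.5)^2 - 0.25)
      img <- img - 0.10 * exp(-(p / bw)^2) * lungW
    }
  }

  if (cfg@noiseSD > 0) img <- img + rnorm(S * S, sd = cfg@noiseSD)
  list(img = img, mask = mask)
}

#' Generate synthetic chest phantoms
#'
#' Deterministic per seed. Each phantom is composed of a smooth vertical
#' background gradient, two bright elliptical lung fields with seeded
#' position and shape jitter, \code{ribCount} darker curved bands crossing
#' the lungs, and additive Gaussian noise of standard deviation
#' \code{noiseSD}, clipped to \code{[0, 1]}. The fraction of clipped pixels
#' is recorded in the \code{clipFraction} attribute (well under 1\% at the
#' default noise level).
#'
#' @param cfg a [PhantomConfig-class].
#' @param withMasks also return the binary lung-field masks as a
#'   \code{masks} attribute ((n, S, S) logical array).
#' @return an [ImageBatch-class] of \code{nImages} phantoms.
#' @export
generatePhantoms <- function(cfg = phantomConfig(), withMasks = FALSE) {
  stopifnot(is(cfg, "PhantomConfig"))
  S <- cfg@imageSize
  n <- cfg@nImages
  .withSeed(cfg@seed, {
    imgs <- array(0, c(n, S, S))
    masks <- if (withMasks) array(FALSE, c(n, S, S))
    clipped <- 0L
    for (b in seq_len(n)) {
      ph <- .onePhantom(S, cfg)
      clipped <- clipped + sum(ph$img < 0 | ph$img > 1)
      imgs[b, , ] <- pmin(pmax(ph$img, 0), 1)
      if (withMasks) masks[b, , ] <- ph$mask
    }
    batch <- ImageBatch(imgs, sprintf("phantom-seed%d-%04d", cfg@seed,
                                      seq_len(n)))
    attr(batch, "clipFraction") <- clipped / (n * S * S)
    if (withMasks) attr(batch, "masks") <- masks
    batch
  })
}
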