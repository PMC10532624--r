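# Learnable components: sinusoidal time embedding, dense-ResNet encoder,
# Bernoulli-logit decoder, FiLM-conditioned score network.
#
# There is no autodiff in this stack, so every forward pass has a matching
# analytic backward pass (verified against finite differences in the tests).
# Parameters live in a flat named list of matrices/vectors; gradients use the
# same names. Images are flattened column-major to length imageSize^2.

# ---------------------------------------------------------------------------
# primitives

.swish <- function(x) x * plogis(x)

.swishGrad <- function(x) {
  s <- plogis(x)
  s * (1 + x * (1 - s))
}

.gadd <- function(G, name, val) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

.denseFwd <- function(X, params, nm) {
  sweep(X %*% params[[paste0(nm, ".W")]], 2L, params[[paste0(nm, ".b")]], "+")
}

# dY -> dX, accumulating weight grads
.denseBwd <- function(dY, X, params, nm, G) {
  .gadd(G, paste0(nm, ".W"), crossprod(X, dY))
  .gadd(G, paste0(nm, ".b"), colSums(dY))
  dY %*% t(params[[paste0(nm, ".W")]])
}

# plain residual block: out = H + dense2(swish(dense1(H)))
.resStackFwd <- function(H, params, prefix, nBlocks) {
  caches <- vector("list", nBlocks)
  for (k in seq_len(nBlocks)) {
    nm <- sprintf("%s%d", prefix, k)
    h1 <- .denseFwd(H, params, paste0(nm, ".l1"))
    A <- .swish(h1)
    R <- .denseFwd(A, params, paste0(nm, ".l2"))
    caches[[k]] <- list(H = H, h1 = h1, A = A)
    H <- H + R
  }
  list(H = H, caches = caches)
}

.resStackBwd <- function(dH, caches, params, prefix, nBlocks, G) {
  for (k in rev(seq_len(nBlocks))) {
    nm <- sprintf("%s%d", prefix, k)
    cc <- caches[[k]]
    dA <- .denseBwd(dH, cc$A, params, paste0(nm, ".l2"), G)
    dh1 <- dA * .swishGrad(cc$h1)
    dH <- dH + .denseBwd(dh1, cc$H, params, paste0(nm, ".l1"), G)
  }
  dH
}

# FiLM residual block: pre-activation h1 is modulated as h1*(1+scale)+shift,
# scale/shift produced by a dense map from the conditioning vector.
.filmStackFwd <- function(H, C, params, prefix, nBlocks) {
  D <- ncol(H)
  caches <- vector("list", nBlocks)
  for (k in seq_len(nBlocks)) {
    nm <- sprintf("%s%d", prefix, k)
    h1 <- .denseFwd(H, params, paste0(nm, ".l1"))
    film <- .denseFwd(C, params, paste0(nm, ".film"))
    g <- film[, seq_len(D), drop = FALSE]
    be <- film[, D + seq_len(D), drop = FALSE]
    f <- h1 * (1 + g) + be
    A <- .swish(f)
    R <- .denseFwd(A, params, paste0(nm, ".l2"))
    caches[[k]] <- list(H = H, h1 = h1, g = g, f = f, A = A)
    H <- H + R
  }
  list(H = H, caches = caches)
}

.filmStackBwd <- function(dH, C, caches, params, prefix, nBlocks, G) {
  D <- ncol(dH)
  dC <- 0
  for (k in rev(seq_len(nBlocks))) {
    nm <- sprintf("%s%d", prefix, k)
    cc <- caches[[k]]
    dA <- .denseBwd(dH, cc$A, params, paste0(nm, ".l2"), G)
    df <- dA * .swishGrad(cc$f)
    dh1 <- df * (1 + cc$g)
    dfilm <- cbind(df * cc$h1, df)
    dC <- dC + .denseBwd(dfilm, C, params, paste0(nm, ".film"), G)
    dH <- dH + .denseBwd(dh1, cc$H, params, paste0(nm, ".l1"), G)
  }
  list(dH = dH, dC = dC)
}

# ---------------------------------------------------------------------------
# parameter initialisation

.denseInit <- function(fanIn, fanOut, zero = FALSE) {
  W <- if (zero) matrix(0, fanIn, fanOut)
       else matrix(rnorm(fanIn * fanOut, sd = sqrt(1 / fanIn)), fanIn, fanOut)
  list(W = W, b = numeric(fanOut))
}

.addDense <- function(params, nm, fanIn, fanOut, zero = FALSE) {
  d <- .denseInit(fanIn, fanOut, zero)
  params[[paste0(nm, ".W")]] <- d$W
  params[[paste0(nm, ".b")]] <- d$b
  params
}

#' Initialise model parameters
#'
#' Builds the flat named list of weight matrices and bias vectors for the
#' encoder, decoder and score network of a [ModelConfig-class]. Dense weights
#' are N(0, 1/fanIn); the closing layer of every residual branch and the two
#' output projections of the score network start at zero, so the score
#' network predicts zero noise at initialisation (stable early training).
#'
#' @param config a [ModelConfig-class].
#' @param seed RNG seed for the random initialisation.
#' @return named list of parameter tensors.
#' @seealso [paramCount()], [encodeImages()], [decodeLatents()], [scoreNet()]
#' @export
initModelParams <- function(config, seed = 0L) {
  stopifnot(is(config, "ModelConfig"))
  npix <- config@imageSize^2
  D <- config@latentDim
  E <- config@scoreEmbeddingDim
  .withSeed(seed, {
    p <- list()
    p <- .addDense(p, "enc.in", npix, D)
    for (k in seq_len(config@encoderBlocks)) {
      p <- .addDense(p, sprintf("enc.res%d.l1", k), D, D)
      p <- .addDense(p, sprintf("enc.res%d.l2", k), D, D, zero = TRUE)
    }
    p <- .addDense(p, "enc.out", D, D)
    p <- .addDense(p, "dec.in", D, D)
    for (k in seq_len(config@decoderBlocks)) {
      p <- .addDense(p, sprintf("dec.res%d.l1", k), D, D)
      p <- .addDense(p, sprintf("dec.res%d.l2", k), D, D, zero = TRUE)
    }
    p <- .addDense(p, "dec.out", D, npix)
    p <- .addDense(p, "sc.c1", E + config@condDim, E)
    p <- .addDense(p, "sc.c2", E, E)
    p <- .addDense(p, "sc.c3", E, E)
    p <- .addDense(p, "sc.in", D, D)
    for (k in seq_len(config@scoreLayers)) {
      p <- .addDense(p, sprintf("sc.res%d.l1", k), D, D)
      p <- .addDense(p, sprintf("sc.res%d.film", k), E, 2L * D)
      p <- .addDense(p, sprintf("sc.res%d.l2", k), D, D, zero = TRUE)
    }
    p <- .addDense(p, "sc.skip", D, D, zero = TRUE)
    p <- .addDense(p, "sc.out", D, D, zero = TRUE)
    p
  })
}

#' Total parameter count of a configuration
#'
#' A pure function of the [ModelConfig-class]; regression-tested to catch
#' silent architecture drift.
#'
#' @param config a [ModelConfig-class].
#' @return integer parameter count.
#' @export
paramCount <- function(config) {
  npix <- config@imageSize^2
  D <- config@latentDim
  E <- config@scoreEmbeddingDim
  dense <- function(i, o) i * o + o
  res <- 2L * dense(D, D)
  film <- res + dense(E, 2L * D)
  dense(npix, D) + config@encoderBlocks * res + dense(D, D) +   # encoder
    dense(D, D) + config@decoderBlocks * res + dense(D, npix) + # decoder
    dense(E + config@condDim, E) + 2L * dense(E, E) +           # cond MLP
    dense(D, D) + config@scoreLayers * film + 2L * dense(D, D)  # score net
}

# ---------------------------------------------------------------------------
# time embedding

#' Sinusoidal time embedding
#'
#' First half \code{sin(w_k t)}, second half \code{cos(w_k t)} with
#' geometrically spaced frequencies \code{10^0 ... 10^4}. Deterministic and
#' injective in practice over \code{[0, 1]}.
#'
#' @param t numeric vector of scalars to embed (times, or gamma values for
#'   the score network's conditioning).
#' @param dim even embedding dimension.
#' @return matrix \code{length(t) x dim}.
#' @export
timeEmbedding <- function(t, dim) {
  if (dim %% 2L != 0L || dim < 2L)
    stop("embedding dim must be a positive even number", call. = FALSE)
  half <- dim %/% 2L
  w <- if (half == 1L) 1 else 10^(4 * (seq_len(half) - 1) / (half - 1))
  ang <- outer(t, w)
  cbind(sin(ang), cos(ang))
}

# ---------------------------------------------------------------------------
# encoder / decoder / score net forward passes (with caches) and backward

.asImageMatrix <- function(x, config) {
  npix <- config@imageSize^2
  if (is(x, "ImageBatch")) x <- intensities(x)
  if (is.matrix(x) && ncol(x) == npix) return(x)
  d <- dim(x)
  if (is.null(d) && length(x) == npix) return(matrix(x, 1L))
  if (length(d) == 2L && all(d == config@imageSize))
    return(matrix(as.vector(x), 1L))
  if (length(d) == 3L && d[2L] == config@imageSize && d[3L] == config@imageSize)
    return(matrix(x, d[1L], npix))
  stop(sprintf("cannot interpret input of shape (%s) as %dx%d images",
               paste(if (is.null(d)) length(x) else d, collapse = ", "),
               config@imageSize, config@imageSize), call. = FALSE)
}

.encFwd <- function(x2d, params, config) {
  H0 <- .denseFwd(x2d, params, "enc.in")
  st <- .resStackFwd(H0, params, "enc.res", config@encoderBlocks)
  out <- .denseFwd(st$H, params, "enc.out")
  list(out = out, x2d = x2d, H0 = H0, stack = st)
}

.encBwd <- function(dOut, fwd, params, config, G) {
  dH <- .denseBwd(dOut, fwd$stack$H, params, "enc.out", G)
  dH0 <- .resStackBwd(dH, fwd$stack$caches, params, "enc.res",
                      config@encoderBlocks, G)
  .denseBwd(dH0, fwd$x2d, params, "enc.in", G)
  invisible(NULL)
}

.decFwd <- function(z, params, config) {
  H0 <- .denseFwd(z, params, "dec.in")
  st <- .resStackFwd(H0, params, "dec.res", config@decoderBlocks)
  logits <- .denseFwd(st$H, params, "dec.out")
  list(out = logits, z = z, H0 = H0, stack = st)
}

.decBwd <- function(dLogits, fwd, params, config, G) {
  dH <- .denseBwd(dLogits, fwd$stack$H, params, "dec.out", G)
  dH0 <- .resStackBwd(dH, fwd$stack$caches, params, "dec.res",
                      config@decoderBlocks, G)
  .denseBwd(dH0, fwd$z, params, "dec.in", G)   # dL/dz
}

.scoreFwd <- function(z, gt, cond, params, config) {
  if (length(gt) == 1L) gt <- rep(gt, nrow(z))
  if (length(gt) != nrow(z))
    stop("gt must be scalar or one value per row of z", call. = FALSE)
  temb <- timeEmbedding(gt, config@scoreEmbeddingDim)
  if (config@condDim > 0L) {
    if (is.null(cond))
      cond <- matrix(0, nrow(z), config@condDim)
    if (!is.matrix(cond)) cond <- matrix(cond, nrow(z), length(cond),
                                         byrow = TRUE)
    if (ncol(cond) != config@condDim)
      stop(sprintf("conditioning must have %d column(s)", config@condDim),
           call. = FALSE)
    X0 <- cbind(temb, cond)
  } else X0 <- temb
  c1z <- .denseFwd(X0, params, "sc.c1"); C1 <- .swish(c1z)
  c2z <- .denseFwd(C1, params, "sc.c2"); C2 <- .swish(c2z)
  C <- .denseFwd(C2, params, "sc.c3")
  H0 <- .denseFwd(z, params, "sc.in")
  st <- .filmStackFwd(H0, C, params, "sc.res", config@scoreLayers)
  out <- z %*% params[["sc.skip.W"]] +
    sweep(st$H %*% params[["sc.out.W"]], 2L, params[["sc.out.b"]], "+")
  list(out = out, z = z, X0 = X0, c1z = c1z, C1 = C1, c2z = c2z, C2 = C2,
       C = C, H0 = H0, stack = st)
}

.scoreBwd <- function(dOut, fwd, params, config, G) {
  .gadd(G, "sc.skip.W", crossprod(fwd$z, dOut))
  .gadd(G, "sc.out.W", crossprod(fwd$stack$H, dOut))
  .gadd(G, "sc.out.b", colSums(dOut))
  dH <- dOut %*% t(params[["sc.out.W"]])
  fb <- .filmStackBwd(dH, fwd$C, fwd$stack$caches, params, "sc.res",
                      config@scoreLayers, G)
  dz <- .denseBwd(fb$dH, fwd$z, params, "sc.in", G) +
    dOut %*% t(params[["sc.skip.W"]])
  dC2 <- .denseBwd(fb$dC, fwd$C2, params, "sc.c3", G)
  dc2z <- dC2 * .swishGrad(fwd$c2z)
  dC1 <- .denseBwd(dc2z, fwd$C1, params, "sc.c2", G)
  dc1z <- dC1 * .swishGrad(fwd$c1z)
  .denseBwd(dc1z, fwd$X0, params, "sc.c1", G)
  dz   # gradient wrt the noisy latent input
}

# ---------------------------------------------------------------------------
# public wrappers

#' Encode images to latents
#'
#' Dense projection of the flattened pixels followed by a stack of residual
#' blocks (two swish dense layers each, additive skip) and a closing dense
#' layer. Deterministic given parameters and inputs.
#'
#' @param x an [ImageBatch-class], an (n, S, S) array, an S x S matrix, or an
#'   already-flattened (n, S^2) matrix.
#' @param params parameter list from [initModelParams()].
#' @param config the matching [ModelConfig-class].
#' @param t optional time conditioning hook; unused by the default
#'   architecture and ignored.
#' @return latent matrix (n, latentDim).
#' @export
encodeImages <- function(x, params, config, t = NULL) {
  .encFwd(.asImageMatrix(x, config), params, config)$out
}

#' Decode latents to Bernoulli pixel logits
#'
#' Residual stack plus a dense map from the latent space to the image space.
#' The observational model is mean-field Bernoulli: each pixel is an
#' independent Bernoulli with probability \code{plogis(logit)}; there is no
#' cross-pixel coupling in the likelihood.
#'
#' @param z latent matrix (n, latentDim).
#' @param params,config as in [encodeImages()].
#' @return logits array (n, imageSize, imageSize).
#' @export
decodeLatents <- function(z, params, config) {
  if (!is.matrix(z)) z <- matrix(z, 1L)
  if (ncol(z) != config@latentDim)
    stop(sprintf("z must have %d columns", config@latentDim), call. = FALSE)
  logits <- .decFwd(z, params, config)$out
  array(logits, c(nrow(z), config@imageSize, config@imageSize))
}

#' Score network (noise prediction)
#'
#' Predicts the standard-normal noise contained in a noisy latent. The
#' conditioning vector is built from the sinusoidal embedding of the
#' log-noise level \code{gt} (concatenated with any extra conditioning),
#' passed through two swish dense layers and a linear closing layer, and
#' applied FiLM-style (per-feature scale and shift of each residual block's
#' pre-activation). The output adds a dense projection of the input to the
#' residual stack's output.
#'
#' @param z noisy latent matrix (n, latentDim).
#' @param gt log-noise level gamma at the noising time; scalar or one value
#'   per row.
#' @param params,config as in [encodeImages()].
#' @param conditioning optional extra conditioning (n, condDim).
#' @return predicted noise, same shape as \code{z}.
#' @export
scoreNet <- function(z, gt, params, config, conditioning = NULL) {
  if (!is.matrix(z)) z <- matrix(z, 1L)
  if (ncol(z) != config@latentDim)
    stop(sprintf("z must have %d columns", config@latentDim), call. = FALSE)
  .scoreFwd(z, gt, conditioning, params, config)$out
}
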