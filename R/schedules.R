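# Schedule evaluation: linear interpolation on gamma, and the learned
# monotonic network (softplus-reparameterised weights; monotone by
# construction for arbitrary raw parameters, then endpoint-rescaled).

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

.checkTimes <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("times must be finite numerics", call. = FALSE)
  if (any(t < 0 | t > 1))
    stop("times must lie in [0, 1]", call. = FALSE)
  invisible(t)
}

# Raw (unrescaled) monotone network: softplus(w0) * t + W2+ . sigmoid(W1+ t + b1)
.rawMonotone <- function(schedule, t) {
  w <- schedule@weights
  pos1 <- .softplus(w$W1)
  pos2 <- .softplus(w$W2)
  hid <- plogis(outer(pos1, t) + w$b1)      # hidden x length(t)
  as.numeric(crossprod(hid, pos2)) + .softplus(w$w0) * t
}

#' @rdname gammaAt
setMethod("gammaAt", "LinearGammaSchedule", function(schedule, t) {
  .checkTimes(t)
  schedule@gammaMin + t * (schedule@gammaMax - schedule@gammaMin)
})

#' @rdname gammaAt
setMethod("gammaAt", "LearnedGammaSchedule", function(schedule, t) {
  .checkTimes(t)
  g <- .rawMonotone(schedule, t)
  g01 <- .rawMonotone(schedule, c(0, 1))
  frac <- (g - g01[1L]) / (g01[2L] - g01[1L])
  out <- schedule@gammaMin + frac * (schedule@gammaMax - schedule@gammaMin)
  # exact endpoints regardless of floating-point cancellation
  out[t == 0] <- schedule@gammaMin
  out[t == 1] <- schedule@gammaMax
  out
})

#' @rdname gammaPrimeAt
setMethod("gammaPrimeAt", "LinearGammaSchedule", function(schedule, t) {
  .checkTimes(t)
  rep(schedule@gammaMax - schedule@gammaMin, length(t))
})

#' @rdname gammaPrimeAt
setMethod("gammaPrimeAt", "LearnedGammaSchedule", function(schedule, t) {
  .checkTimes(t)
  h <- 1e-5
  lo <- pmax(t - h, 0)
  hi <- pmin(t + h, 1)
  (gammaAt(schedule, hi) - gammaAt(schedule, lo)) / (hi - lo)
})

#' Tabulate a schedule on its evaluation grid
#'
#' The reference recipe tabulates gamma on \code{nGrid} linearly spaced steps,
#' each divided into \code{nSubsteps} substeps (50 x 1000 by default). The
#' grid is a tabulation device; continuous evaluation always uses
#' [gammaAt()] directly.
#'
#' @param schedule a [GammaSchedule-class].
#' @return a data.frame with columns \code{t} and \code{gamma},
#'   \code{(nGrid - 1) * nSubsteps + 1} rows.
#' @export
gammaGrid <- function(schedule) {
  n <- (schedule@nGrid - 1L) * schedule@nSubsteps
  t <- seq(0, 1, length.out = n + 1L)
  data.frame(t = t, gamma = gammaAt(schedule, t))
}

#' Monotonic noise-schedule network
#'
#' Evaluates the learned monotonic network of a [GammaSchedule-class] at
#' arbitrary times. The network is a dense layer with
#' softplus-reparameterised (hence nonnegative) weights and sigmoid
#' activations plus a strictly positive linear term, so its output is
#' nondecreasing in \code{t} for every raw parameter setting; an affine
#' rescaling pins the endpoints to \code{gammaMin} and \code{gammaMax}.
#'
#' @param t times in \code{[0, 1]}.
#' @param schedule a \code{LearnedGammaSchedule}.
#' @return gamma values, same length as \code{t}.
#' @export
monotonicGammaNet <- function(t, schedule) {
  stopifnot(is(schedule, "LearnedGammaSchedule"))
  gammaAt(schedule, t)
}
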