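# Closed-form Gaussian algebra of the variance-preserving forward process.
# With sigma_t^2 = plogis(gamma(t)) and alpha_t^2 = plogis(-gamma(t)):
#   marginal     q(z_t | x)      = N(alpha_t x, sigma_t^2 I)
#   transition   q(z_t | z_s)    = N(alpha_ts z_s, sigma2_ts I)
#   posterior    q(z_s | z_t, x) = N(mean, var I)   (Bayes rule)

# fast internal path: no S4 construction, used by losses and the sampler
.alphaSigma <- function(gamma) {
  sigma2 <- plogis(gamma)
  list(alpha = sqrt(plogis(-gamma)), sigma = sqrt(sigma2), sigma2 = sigma2)
}

.checkGamma <- function(gamma) {
  if (!is.numeric(gamma) || any(!is.finite(gamma)))
    stop("gamma must be finite", call. = FALSE)
  invisible(gamma)
}

#' Marginal coefficients of the forward process
#'
#' Maps the log-noise parameter gamma to the coefficients of
#' \code{q(z_t | x) = N(alpha_t x, sigma_t^2 I)} under the
#' variance-preserving convention \code{sigma_t^2 = plogis(gamma)},
#' \code{alpha_t^2 = 1 - sigma_t^2}, so that
#' \code{alpha_t^2 / sigma_t^2 = exp(-gamma)}.
#'
#' @param gamma finite numeric vector of log-noise levels.
#' @return a [MarginalParams-class] (vectorised over \code{gamma}).
#' @examples
#' marginalParams(0)      # alpha = sigma = sqrt(0.5)
#' @export
marginalParams <- function(gamma) {
  .checkGamma(gamma)
  p <- .alphaSigma(gamma)
  new("MarginalParams", alpha = p$alpha, sigma = p$sigma)
}

#' Signal-to-noise ratio
#'
#' \code{alpha^2 / sigma^2 = exp(-gamma)}: strictly decreasing in gamma, and
#' therefore strictly decreasing along forward time for any valid schedule.
#'
#' @inheritParams marginalParams
#' @return numeric vector of SNR values.
#' @export
snr <- function(gamma) {
  .checkGamma(gamma)
  exp(-gamma)
}

#' Draw from the forward process
#'
#' \code{z_t = alpha_t x + sigma_t noise}, elementwise. \code{t} may be a
#' scalar (applied to the whole tensor) or, when \code{x} is a matrix with one
#' row per instance, a vector with one time per row.
#'
#' @param x clean tensor (vector, matrix, or array).
#' @param t time(s) in \code{[0, 1]}.
#' @param noise standard-normal tensor, same shape as \code{x}.
#' @param schedule a [GammaSchedule-class].
#' @return noisy tensor \code{z_t}, same shape as \code{x}.
#' @export
forwardSample <- function(x, t, noise, schedule) {
  if (!identical(dim(x), dim(noise)) || length(x) != length(noise))
    stop("noise must have the same shape as x", call. = FALSE)
  .checkTimes(t)
  p <- .alphaSigma(gammaAt(schedule, t))
  if (length(t) == 1L) return(p$alpha * x + p$sigma * noise)
  if (!is.matrix(x) || nrow(x) != length(t))
    stop("vector t requires a matrix x with one row per time", call. = FALSE)
  x * p$alpha + noise * p$sigma
}

#' Transition coefficients q(z_t | z_s)
#'
#' For \code{0 <= s <= t <= 1}: \code{alphaTS = alpha_t / alpha_s} and
#' \code{sigma2TS = sigma_t^2 - alphaTS^2 sigma_s^2}. Composing this
#' transition over \code{q(z_s | x)} recovers the marginal \code{q(z_t | x)}.
#'
#' @param s,t times with \code{s <= t}.
#' @param schedule a [GammaSchedule-class].
#' @return a [TransitionParams-class].
#' @export
transitionParams <- function(s, t, schedule) {
  .checkTimes(c(s, t))
  if (any(s > t)) stop("transition requires s <= t", call. = FALSE)
  ps <- .alphaSigma(gammaAt(schedule, s))
  pt <- .alphaSigma(gammaAt(schedule, t))
  alphaTS <- pt$alpha / ps$alpha
  sigma2TS <- pmax(pt$sigma2 - alphaTS^2 * ps$sigma2, 0)
  new("TransitionParams", alphaTS = alphaTS, sigma2TS = sigma2TS)
}

# posterior coefficients as plain numbers (sampler hot path)
.posteriorCoef <- function(s, t, schedule) {
  ps <- .alphaSigma(gammaAt(schedule, s))
  pt <- .alphaSigma(gammaAt(schedule, t))
  alphaTS <- pt$alpha / ps$alpha
  sigma2TS <- max(pt$sigma2 - alphaTS^2 * ps$sigma2, 0)
  list(coefZ = alphaTS * ps$sigma2 / pt$sigma2,
       coefX = ps$alpha * sigma2TS / pt$sigma2,
       var = sigma2TS * ps$sigma2 / pt$sigma2,
       alphaT = pt$alpha, sigmaT = pt$sigma)
}

#' Bayes posterior q(z_s | z_t, x)
#'
#' Gaussian conjugacy of transition and marginal gives
#' \code{variance = sigma2TS sigma_s^2 / sigma_t^2} and
#' \code{mean = (alphaTS sigma_s^2 / sigma_t^2) z_t +
#' (alpha_s sigma2TS / sigma_t^2) x}. The variance never exceeds
#' \code{sigma_s^2}: conditioning on \code{z_t} cannot add uncertainty.
#'
#' @param zt noisy tensor at time \code{t}.
#' @param x clean tensor, same shape as \code{zt}.
#' @param s,t times with \code{0 <= s < t <= 1}.
#' @param schedule a [GammaSchedule-class].
#' @return a [PosteriorParams-class].
#' @export
posteriorParams <- function(zt, x, s, t, schedule) {
  .checkTimes(c(s, t))
  if (length(s) != 1L || length(t) != 1L)
    stop("s and t must be scalars", call. = FALSE)
  if (s >= t) stop("posterior requires s < t", call. = FALSE)
  if (length(zt) != length(x))
    stop("zt and x must have the same shape", call. = FALSE)
  pc <- .posteriorCoef(s, t, schedule)
  new("PosteriorParams", mean = pc$coefZ * zt + pc$coefX * x,
      variance = pc$var)
}
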