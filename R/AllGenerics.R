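#' @import methods
#' @importFrom stats rnorm runif plogis qlogis integrate dnorm sd
NULL

#' Evaluate a noise schedule
#'
#' Maps diffusion time \code{t} in \code{[0, 1]} to the log-signal-to-noise
#' parameter gamma. Gamma is nondecreasing in \code{t}: the signal-to-noise
#' ratio \code{exp(-gamma)} decreases as the forward process adds noise.
#'
#' @param schedule a [GammaSchedule-class] object.
#' @param t numeric vector of times in \code{[0, 1]}.
#' @return numeric vector of gamma values, same length as \code{t}.
#' @seealso [linearGammaSchedule()], [learnedGammaSchedule()], [gammaPrimeAt()]
#' @export
setGeneric("gammaAt", function(schedule, t) standardGeneric("gammaAt"))

#' Derivative of a noise schedule
#'
#' \code{d gamma / d t}, used as the weight of the continuous-time diffusion
#' loss. Exact for the linear schedule; central finite differences for the
#' learned monotonic network (step 1e-5, one-sided at the endpoints).
#'
#' @inheritParams gammaAt
#' @return numeric vector of derivatives, same length as \code{t}.
#' @export
setGeneric("gammaPrimeAt", function(schedule, t) standardGeneric("gammaPrimeAt"))

#' @rdname ImageBatch-class
#' @param x an \code{ImageBatch}.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ImageBatch-class
#' @export
setGeneric("sourceTags", function(x) standardGeneric("sourceTags"))

#' @rdname ImageBatch-class
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname LossBreakdown-class
#' @param object a \code{LossBreakdown}.
#' @export
setGeneric("lossTerms", function(object) standardGeneric("lossTerms"))

#' @rdname LossBreakdown-class
#' @export
setGeneric("lossWeights", function(object) standardGeneric("lossWeights"))

#' @rdname LossBreakdown-class
#' @export
setGeneric("lossTotal", function(object) standardGeneric("lossTotal"))
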