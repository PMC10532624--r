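# AdamW training loop: linear warmup times cosine decay as multiplicative
# factors on the base learning rate, decoupled weight decay on matrices
# only, seeded batching, checkpointing with full RNG state.

#' Learning rate at a step
#'
#' \code{baseLR * warmup(step) * cosine(step)} where the warmup factor rises
#' linearly from 0 to 1 over \code{warmupSteps} and the cosine factor decays
#' from 1 to \code{finalDecay} via
#' \code{finalDecay + (1 - finalDecay) * 0.5 * (1 + cos(pi step / totalSteps))}.
#' Steps beyond \code{totalSteps} clamp to the terminal value.
#'
#' @param step nonnegative step counter.
#' @param cfg a [TrainConfig-class].
#' @return learning rate (vectorised over \code{step}).
#' @export
lrAt <- function(step, cfg) {
  stopifnot(is(cfg, "TrainConfig"))
  if (any(step < 0)) stop("step must be >= 0", call. = FALSE)
  s <- pmin(step, cfg@totalSteps)
  warm <- pmin(1, step / cfg@warmupSteps)
  cosf <- cfg@finalDecay +
    (1 - cfg@finalDecay) * 0.5 * (1 + cos(pi * s / cfg@totalSteps))
  cfg@baseLR * warm * cosf
}

# parameter names subject to decoupled weight decay: matrices only,
# never bias vectors. A pure function of the parameter inventory.
.decayedNames <- function(params) {
  names(params)[vapply(params, is.matrix, logical(1))]
}

.adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamwStep <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg@b1^state$t
  bc2 <- 1 - cfg@b2^state$t
  decay <- .decayedNames(params)
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg@b1 * state$m[[nm]] + (1 - cfg@b1) * g
    state$v[[nm]] <- cfg@b2 * state$v[[nm]] + (1 - cfg@b2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg@eps)
    if (nm %in% decay) upd <- upd + cfg@weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

.historyRow <- function(step, bd, lr) {
  t <- lossTerms(bd)
  data.frame(step = step, reconstruction = t[["reconstruction"]],
             diffusion = t[["diffusion"]], latent = t[["latent"]],
             differential = t[["differential"]], total = lossTotal(bd),
             lr = lr)
}

#' Train the diffusion model
#'
#' Runs \code{totalSteps} AdamW updates of the full objective
#' ([totalLoss()]) on seeded batches. Batching reshuffles the dataset each
#' epoch with the training RNG; no augmentation is applied. The loss
#' breakdown is logged every \code{logEvery} steps (and at steps 0 and
#' \code{totalSteps}). Runs are bit-reproducible per seed; resuming from a
#' checkpoint reproduces the uninterrupted run exactly, including the RNG
#' stream.
#'
#' @param data an [ImageBatch-class] (or (n, S, S) array) of training images.
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param schedule a [GammaSchedule-class]; held fixed during training.
#' @param weights loss weights as in [totalLoss()].
#' @param logEvery logging interval in steps.
#' @param params optional initial parameters (default: fresh
#'   [initModelParams()] under the training seed).
#' @param resumeFrom optional checkpoint (list from [loadCheckpoint()]) to
#'   continue from.
#' @param checkpointPath optional path; the final checkpoint is written
#'   there with [saveCheckpoint()].
#' @param stopAtStep optional early stop (for mid-run checkpointing); the
#'   learning-rate horizon stays \code{totalSteps}.
#' @return invisibly, a list with \code{params}, \code{optState},
#'   \code{step}, \code{history} (data.frame of logged
#'   [LossBreakdown-class] terms), \code{modelCfg}, \code{trainCfg},
#'   \code{scheduleGammaRange}, and \code{rngState}.
#' @export
trainVDM <- function(data, modelCfg, trainCfg = trainConfig(),
                     schedule = linearGammaSchedule(), weights = NULL,
                     logEvery = 50L, params = NULL, resumeFrom = NULL,
                     checkpointPath = NULL, stopAtStep = NULL) {
  w <- .checkWeights(weights)
  x2d <- .asImageMatrix(data, modelCfg)
  n <- nrow(x2d)
  if (n < 1L) stop("dataset must be nonempty", call. = FALSE)
  B <- min(trainCfg@batchSize, n)

  hasOld <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (hasOld) oldSeed <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (hasOld) assign(".Random.seed", oldSeed, globalenv()))

  order <- NULL
  pos <- Inf
  if (!is.null(resumeFrom)) {
    params <- resumeFrom$params
    opt <- resumeFrom$optState
    startStep <- resumeFrom$step
    history <- resumeFrom$history
    order <- resumeFrom$batchOrder
    pos <- resumeFrom$batchPos
    assign(".Random.seed", resumeFrom$rngState, globalenv())
  } else {
    set.seed(trainCfg@seed)
    if (is.null(params)) params <- initModelParams(modelCfg, trainCfg@seed)
    opt <- .adamwInit(params)
    startStep <- 0L
    history <- NULL
    bd0 <- .lossCore(x2d[sample.int(n, B), , drop = FALSE], params, modelCfg,
                     schedule, w)$breakdown
    history <- .historyRow(0L, bd0, lrAt(0L, trainCfg))
  }

  lastStep <- if (is.null(stopAtStep)) trainCfg@totalSteps
              else min(stopAtStep, trainCfg@totalSteps)
  for (step in seq(startStep + 1L, length.out = max(0L, lastStep - startStep))) {
    if (pos + B - 1L > n) { order <- sample.int(n); pos <- 1L }
    idx <- order[pos:(pos + B - 1L)]
    pos <- pos + B
    res <- .lossCore(x2d[idx, , drop = FALSE], params, modelCfg, schedule, w,
                     computeGrad = TRUE)
    if (!is.finite(lossTotal(res$breakdown)))
      stop(sprintf("non-finite loss at step %d: %s", step,
                   paste(sprintf("%s=%g", names(lossTerms(res$breakdown)),
                                 lossTerms(res$breakdown)), collapse = " ")),
           call. = FALSE)
    lr <- lrAt(step, trainCfg)
    up <- .adamwStep(params, res$grads, opt, lr, trainCfg)
    params <- up$params
    opt <- up$state
    if (step %% logEvery == 0L || step == lastStep)
      history <- rbind(history, .historyRow(step, res$breakdown, lr))
  }

  out <- list(params = params, optState = opt, step = lastStep,
              history = history, modelCfg = modelCfg, trainCfg = trainCfg,
              scheduleGammaRange = c(schedule@gammaMin, schedule@gammaMax),
              batchOrder = order, batchPos = pos,
              rngState = get(".Random.seed", globalenv(), inherits = FALSE))
  if (!is.null(checkpointPath)) saveCheckpoint(out, checkpointPath)
  invisible(out)
}

#' Checkpoint input/output
#'
#' A checkpoint is the flat named parameter list plus AdamW state, step
#' counter, RNG state, configs and loss history — everything needed to
#' resume bit-exactly. Stored as an RDS file.
#'
#' @param run result list from [trainVDM()].
#' @param path file path.
#' @return \code{saveCheckpoint}: the path, invisibly;
#'   \code{loadCheckpoint}: the run list.
#' @export
saveCheckpoint <- function(run, path) {
  saveRDS(run, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("no checkpoint at ", path, call. = FALSE)
  readRDS(path)
}

#' Write a loss-history CSV
#'
#' Columns: step, reconstruction, diffusion, latent, differential, total,
#' lr — one row per logged step.
#'
#' @param history data.frame from [trainVDM()].
#' @param path output CSV path.
#' @export
writeLossCSV <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
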