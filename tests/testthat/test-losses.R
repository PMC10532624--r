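# Loss analytics against loop oracles, closed forms, quadrature and
# Monte-Carlo expectations.

test_that("reconstruction loss matches the per-pixel Bernoulli oracle", {
  # maximum-entropy pixel: x = 0.5 at logit 0 costs ln 2
  expect_equal(reconstructionLoss(0.5, 0), log(2), tolerance = 1e-12)
  # perfect-certainty limit
  expect_equal(reconstructionLoss(c(0, 1), c(-Inf, Inf)), 0)
  expect_error(reconstructionLoss(c(-0.1, 0.5), c(0, 0)), "\\[0, 1\\]")
  expect_error(reconstructionLoss(c(0.1, 0.5), 0), "same shape")

  withr::with_seed(1, {
    x <- matrix(runif(16), 4, 4)
    logits <- matrix(rnorm(16, sd = 2), 4, 4)
    loop <- 0
    for (i in 1:4) for (j in 1:4) {
      p <- plogis(logits[i, j])
      loop <- loop - (x[i, j] * log(p) + (1 - x[i, j]) * log(1 - p))
    }
    expect_equal(reconstructionLoss(x, logits), loop, tolerance = 1e-10)
  })
})

test_that("latent KL matches numerical integration and is nonnegative", {
  # sigma_1^2 = 0.5 at x = 0: closed form 0.09657 nats per dimension
  sch <- linearGammaSchedule(-1, 0)
  expect_equal(latentLoss(0, sch), 0.0965735902799727, tolerance = 1e-10)
  # numerical KL integral oracle, per dimension, for several x
  for (x in c(0, 0.4, 1)) {
    p <- oracleAlphaSigma(gammaAt(sch, 1))
    q <- function(z) dnorm(z, p$alpha * x, p$sigma)
    integrand <- function(z) {
      lr <- dnorm(z, p$alpha * x, p$sigma, log = TRUE) - dnorm(z, log = TRUE)
      q(z) * lr
    }
    num <- integrate(integrand, -12, 12, rel.tol = 1e-12)$value
    expect_equal(latentLoss(x, sch), num, tolerance = 1e-6)
  }
  # default schedule: strictly positive for any input, KL >= 0
  def <- linearGammaSchedule()
  withr::with_seed(2, {
    for (k in 1:20) expect_gt(latentLoss(runif(5), def), 0)
  })
  # batch conventions: matrix rows and array images average
  xm <- matrix(c(0.2, 0.8), 2, 3)
  expect_equal(latentLoss(xm, def),
               (latentLoss(xm[1, ], def) + latentLoss(xm[2, ], def)) / 2)
})

test_that("antithetic times stratify exactly one sample per bin", {
  expect_equal(antitheticTimes(4L, 0), c(0, 0.25, 0.5, 0.75))
  expect_equal(antitheticTimes(2L, 0.1), c(0.1, 0.6))
  expect_error(antitheticTimes(0L, 0.5), ">= 1")
  expect_error(antitheticTimes(4L, 1), "\\[0, 1\\)")
  withr::with_seed(3, {
    for (k in 1:1000) {
      n <- sample(2:9, 1)
      tt <- antitheticTimes(n, runif(1))
      bins <- as.integer(floor(tt * n))
      expect_identical(sort(bins), 0:(n - 1))
    }
  })
})

test_that("discrete diffusion loss equals the Gaussian-chain KL on a 1-D toy", {
  sch <- linearGammaSchedule()
  x <- 0.7
  perfect <- function(z, g, t) {
    p <- oracleAlphaSigma(g)
    (z - p$alpha * x) / p$sigma   # recovers the exact noise used to build z
  }
  expect_lt(diffusionLossDiscrete(x, perfect, 8L, sch, nDraws = 500L,
                                  seed = 1L), 1e-20)
  # near-degenerate schedule: expm1(dgamma) ~ 0 kills the loss
  flat <- linearGammaSchedule(0.5, 0.5 + 1e-12)
  cheat <- function(z, g, t) z * 0
  expect_lt(diffusionLossDiscrete(x, cheat, 4L, flat, nDraws = 500L,
                                  seed = 1L), 1e-9)
  expect_error(diffusionLossDiscrete(x, cheat, 0L, sch), ">= 1")

  pred <- function(z, g, t) 0.4 * z
  for (T in c(1L, 2L, 4L, 8L)) {
    est <- diffusionLossDiscrete(x, pred, T, sch, nDraws = 5e4, seed = T)
    oracle <- chainKLOracle(x, 0.4, T, sch)
    expect_lt(abs(est - oracle), 4 * attr(est, "se"))
  }
})

test_that("continuous diffusion loss matches its expectations", {
  sch <- linearGammaSchedule()
  perfect <- function(z, g, t) {
    p <- oracleAlphaSigma(g)
    sweep(z, 1, p$alpha * 0.3) / p$sigma
  }
  expect_lt(diffusionLossContinuous(0.3, perfect, sch, nTimes = 200L,
                                    seed = 2L), 1e-20)
  # zero predictor in d dimensions: E = 0.5 (gammaMax - gammaMin) d
  zero <- function(z, g, t) z * 0
  est <- diffusionLossContinuous(rep(0, 4), zero, sch, nTimes = 1e4,
                                 seed = 3L)
  expect_lt(abs(est - 0.5 * 0.9 * 4), 4 * attr(est, "se"))
  # discrete losses decrease toward the continuous value (linear toy)
  o <- vapply(c(1L, 2L, 4L, 8L, 64L, 512L),
              function(T) chainKLOracle(0.7, 0.4, T, sch), numeric(1))
  expect_true(all(diff(o) < 0))
  cont <- chainKLContinuousOracle(0.7, 0.4, sch)
  expect_true(all(o > cont))
  expect_equal(o[6], cont, tolerance = 2e-3)
  est <- diffusionLossContinuous(0.7, function(z, g, t) 0.4 * z, sch,
                                 nTimes = 5e4, seed = 4L)
  expect_lt(abs(est - cont), 4 * attr(est, "se"))
})

test_that("differential loss follows the finite-difference definition", {
  withr::with_seed(5, x <- matrix(runif(25), 5, 5))
  expect_equal(differentialLoss(x, x), 0)
  expect_equal(differentialLoss(x, x + 0.3), 0, tolerance = 1e-12)
  expect_error(differentialLoss(matrix(1, 1, 3), matrix(0, 1, 3)), "2x2")
  expect_error(differentialLoss(x, matrix(0, 4, 4)), "same shape")
  # hand-computed 2x2 case: one interior pixel, horizontal gradients 1 vs 0
  x2 <- matrix(c(0, 0, 1, 1), 2, 2)   # rows (0,1),(0,1)
  expect_equal(differentialLoss(x2, matrix(0, 2, 2)), 1)
  # independent loop oracle on a random pair
  withr::with_seed(6, {
    a <- matrix(runif(30), 5, 6)
    b <- matrix(runif(30), 5, 6)
    acc <- 0
    for (i in 1:4) for (j in 1:5) {
      dh <- (a[i, j + 1] - a[i, j]) - (b[i, j + 1] - b[i, j])
      dv <- (a[i + 1, j] - a[i, j]) - (b[i + 1, j] - b[i, j])
      acc <- acc + dh^2 + dv^2
    }
    expect_equal(differentialLoss(a, b), acc / 20, tolerance = 1e-12)
  })
})

test_that("total loss assembles a reproducible weighted breakdown", {
  cfg <- tinyConfig()
  params <- activateParams(initModelParams(cfg, seed = 1L))
  withr::with_seed(7, x <- array(runif(4 * 16), c(4, 4, 4)))
  sch <- linearGammaSchedule()

  bd1 <- totalLoss(x, params, cfg, sch, seed = 9L)
  bd2 <- totalLoss(x, params, cfg, sch, seed = 9L)
  expect_identical(lossTerms(bd1), lossTerms(bd2))
  expect_equal(lossTotal(bd1), sum(lossWeights(bd1) * lossTerms(bd1)))
  expect_gte(lossTerms(bd1)[["diffusion"]], 0)
  expect_gte(lossTerms(bd1)[["latent"]], 0)

  # subset weights: total = recon + diffusion + latent when differential = 0
  bd3 <- totalLoss(x, params, cfg, sch, weights = c(differential = 0),
                   seed = 9L)
  t3 <- lossTerms(bd3)
  expect_identical(t3, lossTerms(bd1))  # same seed, same draws
  expect_equal(lossTotal(bd3),
               t3[["reconstruction"]] + t3[["diffusion"]] + t3[["latent"]])
  # all-zero weights: zero total, breakdown preserved
  bd0 <- totalLoss(x, params, cfg, sch,
                   weights = c(reconstruction = 0, diffusion = 0,
                               latent = 0, differential = 0), seed = 9L)
  expect_identical(lossTotal(bd0), 0)
  expect_identical(lossTerms(bd0), lossTerms(bd1))
  expect_error(totalLoss(x, params, cfg, sch, weights = c(latent = -1)),
               "nonnegative")
  expect_error(totalLoss(x, params, cfg, sch, weights = c(bogus = 1)),
               "named")
})
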