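# Closed-form Gaussian diffusion mathematics, checked against independent
# oracles: the logistic mapping, Monte-Carlo moments, and grid-quadrature
# Bayes inversion.

test_that("linear gamma schedule interpolates exactly and rejects bad times", {
  s <- linearGammaSchedule()
  expect_identical(gammaAt(s, 0), 0.1)
  expect_identical(gammaAt(s, 1), 1.0)
  expect_equal(gammaAt(s, 0.5), 0.55, tolerance = 1e-15)
  expect_equal(gammaAt(s, c(0.2, 0.8)), oracleGammaLinear(c(0.2, 0.8)))
  expect_error(gammaAt(s, -0.01), "\\[0, 1\\]")
  expect_error(gammaAt(s, 1.5), "\\[0, 1\\]")
  expect_error(linearGammaSchedule(1, 0.5), "strictly greater")
  expect_error(linearGammaSchedule(nGrid = 1L), "nGrid")
})

test_that("the tabulation grid covers [0,1] with nGrid x nSubsteps points", {
  s <- linearGammaSchedule(nGrid = 5L, nSubsteps = 10L)
  g <- gammaGrid(s)
  expect_equal(nrow(g), 41L)
  expect_equal(g$t[1], 0)
  expect_equal(g$t[41], 1)
  expect_true(all(diff(g$gamma) >= 0))
  expect_equal(g$gamma, oracleGammaLinear(g$t))
})

test_that("marginal coefficients follow the logistic mapping and preserve variance", {
  m0 <- marginalParams(0)
  expect_equal(m0@alpha, sqrt(0.5), tolerance = 1e-15)
  expect_equal(m0@sigma, sqrt(0.5), tolerance = 1e-15)
  # gamma -> -inf limit: alpha -> 1, sigma -> 0
  mLow <- marginalParams(-40)
  expect_equal(mLow@alpha, 1, tolerance = 1e-9)
  expect_lt(mLow@sigma, 1e-8)
  # independent high-precision logistic evaluation at the default gammaMin
  m <- marginalParams(0.1)
  expect_equal(m@sigma^2, 0.524979187478940, tolerance = 1e-12)
  expect_equal(m@alpha^2, 1 - 0.524979187478940, tolerance = 1e-12)
  expect_error(marginalParams(NaN), "finite")
  expect_error(marginalParams(Inf), "finite")

  # variance preservation for 1e4 random gammas, property from the class
  withr::with_seed(1, {
    g <- runif(1e4, -12, 12)
    mm <- marginalParams(g)
    expect_lt(max(abs(mm@alpha^2 + mm@sigma^2 - 1)), 1e-12)
    expect_true(all(mm@alpha > 0 & mm@sigma > 0))
  })
})

test_that("SNR equals exp(-gamma) and decreases along any schedule", {
  expect_equal(snr(0), 1.0)
  expect_equal(snr(log(4)), 0.25, tolerance = 1e-15)
  expect_equal(snr(1.0), 0.367879441171442, tolerance = 1e-12)
  for (s in list(linearGammaSchedule(),
                 learnedGammaSchedule(seed = 4L),
                 linearGammaSchedule(-8, 8))) {
    tt <- seq(0, 1, length.out = 101)
    expect_true(all(diff(snr(gammaAt(s, tt))) <= 1e-12))
  }
})

test_that("forward sampling matches its Gaussian moments", {
  s <- linearGammaSchedule()
  x <- c(0.2, 0.9)
  expect_error(forwardSample(x, 0.5, c(0, 0, 0), s), "same shape")
  # noiseless limit via a schedule pinned at very low noise
  sLow <- linearGammaSchedule(-40, -39)
  expect_equal(forwardSample(x, 0, rnorm(2), sLow), x, tolerance = 1e-8)
  # alpha -> 0 with zero noise
  sHigh <- linearGammaSchedule(39, 40)
  expect_equal(forwardSample(x, 1, c(0, 0), sHigh), c(0, 0),
               tolerance = 1e-8)
  # Monte-Carlo moments at fixed t within 4 SE
  withr::with_seed(7, {
    n <- 1e5
    t <- 0.6
    p <- oracleAlphaSigma(oracleGammaLinear(t))
    z <- forwardSample(matrix(0.8, n, 1), t, matrix(rnorm(n), n, 1), s)
    expect_lt(abs(mean(z) - p$alpha * 0.8), 4 * p$sigma / sqrt(n))
    expect_lt(abs(sd(z) - p$sigma), 4 * p$sigma / sqrt(2 * n))
  })
})

test_that("transitions compose with marginals (Markov consistency)", {
  sch <- linearGammaSchedule()
  idt <- transitionParams(0.4, 0.4, sch)
  expect_equal(idt@alphaTS, 1)
  expect_equal(idt@sigma2TS, 0)
  expect_error(transitionParams(0.6, 0.4, sch), "s <= t")

  # alpha_ts = alpha_t / alpha_s against the independent mapping
  tr <- transitionParams(0.3, 0.8, sch)
  ps <- oracleAlphaSigma(oracleGammaLinear(0.3))
  pt <- oracleAlphaSigma(oracleGammaLinear(0.8))
  expect_equal(tr@alphaTS, pt$alpha / ps$alpha, tolerance = 1e-12)
  expect_equal(tr@sigma2TS, pt$sigma2 - tr@alphaTS^2 * ps$sigma2,
               tolerance = 1e-12)

  # from a near-clean start the transition is close to the marginal
  schWide <- linearGammaSchedule(-30, 5)
  tr0 <- transitionParams(0, 1, schWide)
  m1 <- oracleAlphaSigma(5)
  expect_equal(tr0@alphaTS, m1$alpha, tolerance = 1e-6)
  expect_equal(tr0@sigma2TS, m1$sigma2, tolerance = 1e-6)

  # two-step composition equals the direct marginal, by MC moments
  withr::with_seed(11, {
    n <- 1e5
    x <- 0.7
    s <- 0.35; t <- 0.9
    zs <- forwardSample(rep(x, n), s, rnorm(n), sch)
    tr <- transitionParams(s, t, sch)
    zt2 <- tr@alphaTS * zs + sqrt(tr@sigma2TS) * rnorm(n)
    pt <- oracleAlphaSigma(oracleGammaLinear(t))
    expect_lt(abs(mean(zt2) - pt$alpha * x), 4 * pt$sigma / sqrt(n))
    expect_lt(abs(sd(zt2) - pt$sigma), 4 * pt$sigma / sqrt(2 * n))
  })
})

test_that("the closed-form posterior matches grid-quadrature Bayes inversion", {
  sch <- linearGammaSchedule()
  expect_error(posteriorParams(0.5, 0.5, 0.7, 0.3, sch), "s < t")
  expect_error(posteriorParams(0.5, 0.5, 0.4, 0.4, sch), "s < t")

  # x = 0: mean proportional to z_t alone
  p0 <- posteriorParams(1.3, 0, 0.2, 0.9, sch)
  p0b <- posteriorParams(2.6, 0, 0.2, 0.9, sch)
  expect_equal(p0b@mean, 2 * p0@mean, tolerance = 1e-12)

  # s -> t limit: mean -> z_t, variance -> 0
  pLim <- posteriorParams(0.8, 0.3, 0.69999, 0.7, sch)
  expect_equal(pLim@mean, 0.8, tolerance = 1e-3)
  expect_lt(pLim@variance, 1e-4)

  withr::with_seed(3, {
    for (k in 1:20) {
      s <- runif(1, 0, 0.85)
      t <- runif(1, s + 0.1, 1)
      x <- runif(1, -1, 1)
      zt <- rnorm(1)
      pp <- posteriorParams(zt, x, s, t, sch)
      expect_lte(pp@variance, oracleAlphaSigma(oracleGammaLinear(s))$sigma2)
      gs <- seq(-8, 8, length.out = 8001)
      ps <- oracleAlphaSigma(oracleGammaLinear(s))
      pt <- oracleAlphaSigma(oracleGammaLinear(t))
      aTS <- pt$alpha / ps$alpha
      s2TS <- pt$sigma2 - aTS^2 * ps$sigma2
      dens <- dnorm(zt, aTS * gs, sqrt(s2TS)) * dnorm(gs, ps$alpha * x, ps$sigma)
      dens <- dens / (sum(dens) * (gs[2] - gs[1]))
      expect_lt(max(abs(dens - dnorm(gs, pp@mean, sqrt(pp@variance)))), 1e-3)
    }
  })
})

test_that("learned monotonic schedule hits its endpoints and never decreases", {
  tt <- sort(runif(200))
  for (seed in 1:20) {
    sch <- learnedGammaSchedule(seed = seed)
    g <- gammaAt(sch, c(0, tt, 1))
    expect_identical(g[1], 0.1)
    expect_identical(g[202], 1.0)
    expect_true(all(diff(g) >= -1e-12))
  }
  # suppressed hidden units leave the strictly positive linear term: the
  # rescaled schedule becomes exact linear interpolation
  w <- list(w0 = 0.3, W1 = rep(-40, 4), b1 = rep(0.2, 4), W2 = rep(0.5, 4))
  sch <- learnedGammaSchedule(hidden = 4L, weights = w)
  tt <- seq(0, 1, by = 0.05)
  expect_equal(gammaAt(sch, tt), oracleGammaLinear(tt), tolerance = 1e-8)
  expect_equal(monotonicGammaNet(tt, sch), gammaAt(sch, tt))
  expect_error(gammaAt(sch, 1.2), "\\[0, 1\\]")
  # derivative of the linear-degenerate learned net is the constant slope
  expect_equal(gammaPrimeAt(sch, c(0.25, 0.75)), c(0.9, 0.9),
               tolerance = 1e-4)
})
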