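# Shared fixtures and independent oracles. Oracles deliberately recompute
# quantities from their defining formulas (logistic mapping, quadrature,
# per-pixel loops) rather than calling the code paths they check.

# independent alpha/sigma from the stated convention sigma^2 = logistic(gamma)
oracleAlphaSigma <- function(gamma) {
  s2 <- 1 / (1 + exp(-gamma))
  list(alpha = sqrt(1 - s2), sigma = sqrt(s2), sigma2 = s2)
}

oracleGammaLinear <- function(t, gmin = 0.1, gmax = 1.0) gmin + t * (gmax - gmin)

# small architecture for network tests
tinyConfig <- function(...) {
  modelConfig(latentDim = 6L, encoderBlocks = 2L, decoderBlocks = 2L,
              scoreEmbeddingDim = 8L, scoreLayers = 2L, imageSize = 4L, ...)
}

# replace exact-zero init tensors with small random values so that every
# pathway (residual branches, score output projections) is active
activateParams <- function(params, seed = 2L, sd = 0.1) {
  withr::with_seed(seed, {
    for (nm in names(params))
      if (all(params[[nm]] == 0))
        params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), sd = sd)
    params
  })
}

# closed-form optimal noise predictor for 1-D data x ~ N(mu0, sd0^2)
gaussianOptimalPredictor <- function(mu0, sd0) {
  function(z, g, t) {
    p <- oracleAlphaSigma(g)
    xpost <- mu0 + (p$alpha * sd0^2 / (p$alpha^2 * sd0^2 + p$sigma2)) *
      (z - p$alpha * mu0)
    (z - p$alpha * xpost) / p$sigma
  }
}

# exact per-step KL oracle for a linear predictor epsHat = c * z on scalar
# data: sum over steps of E_{z_t ~ q(z_t|x)} KL(q(z_s|z_t,x) || p(z_s|z_t)),
# each expectation by adaptive quadrature
chainKLOracle <- function(x, cc, T, schedule) {
  tot <- 0
  for (i in seq_len(T)) {
    s <- (i - 1) / T
    t <- i / T
    ps <- oracleAlphaSigma(gammaAt(schedule, s))
    pt <- oracleAlphaSigma(gammaAt(schedule, t))
    aTS <- pt$alpha / ps$alpha
    s2TS <- pt$sigma2 - aTS^2 * ps$sigma2
    coefX <- ps$alpha * s2TS / pt$sigma2
    v <- s2TS * ps$sigma2 / pt$sigma2
    f <- function(zt) {
      xhat <- (zt - pt$sigma * cc * zt) / pt$alpha
      (coefX * (x - xhat))^2 / (2 * v) * dnorm(zt, pt$alpha * x, pt$sigma)
    }
    tot <- tot + integrate(f, -10, 10, rel.tol = 1e-10)$value
  }
  tot
}

# continuous-time limit of the same toy, by quadrature over t
chainKLContinuousOracle <- function(x, cc, schedule) {
  gp <- schedule@gammaMax - schedule@gammaMin
  integrate(Vectorize(function(t) {
    p <- oracleAlphaSigma(gammaAt(schedule, t))
    0.5 * gp * ((cc * p$alpha * x)^2 + (1 - cc * p$sigma)^2)
  }), 0, 1, rel.tol = 1e-10)$value
}

# 3x3 box blur with edge replication (used by the phantom smoothness check)
boxBlur3 <- function(m) {
  S <- nrow(m)
  p <- rbind(m[1, ], m, m[S, ])
  p <- cbind(p[, 1], p, p[, S])
  (p[1:S, 1:S] + p[1:S, 2:(S + 1)] + p[1:S, 3:(S + 2)] +
   p[2:(S + 1), 1:S] + p[2:(S + 1), 2:(S + 1)] + p[2:(S + 1), 3:(S + 2)] +
   p[3:(S + 2), 1:S] + p[3:(S + 2), 2:(S + 1)] + p[3:(S + 2), 3:(S + 2)]) / 9
}

# empirical W1 distance of samples to N(mu, sd) by quantile matching
w1ToNormal <- function(z, mu, sd) {
  n <- length(z)
  mean(abs(sort(z) - qnorm((seq_len(n) - 0.5) / n, mu, sd)))
}
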