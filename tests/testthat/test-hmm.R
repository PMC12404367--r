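test_that("emission log-density: marginalization, zero-mass, closed form", {
  cfg <- simConfig(seed = 30)
  set.seed(30)
  sim <- simulateSteps(sample(1:3, 20, TRUE), cfg)
  steps <- sim$steps
  pf <- paramsFromConfig(steps, cfg)

  # all streams missing -> log-density 0 for every state
  blank <- steps
  blank[, c("Ms", "Tr", "Sf", "Md", "Rd", "Dp")] <- NA
  ld0 <- emissionLogDensity(blank, pf$spec, pf$params)
  expect_true(all(ld0 == 0))

  # Dp = 0 contributes exactly log z
  one <- blank[1, ]; one$Dp <- 0
  ld1 <- emissionLogDensity(one, pf$spec, pf$params)
  expect_equal(as.numeric(ld1),
               log(plogis(pf$params$emission$Dp$zeta)), tolerance = 1e-12)

  # one-stream record matches the textbook gamma pdf
  one2 <- blank[1, ]; one2$Ms <- 1500
  ld2 <- emissionLogDensity(one2, pf$spec, pf$params)
  ep <- cfg$state_emission_params
  for (k in 1:3) {
    pr <- gammaShapeRate(ep$Ms$mean[k], ep$Ms$sd[k])
    expect_equal(ld2[1, k], dgamma(1500, pr$shape, pr$rate, log = TRUE),
                 tolerance = 1e-10)
  }
  # weibull stream matches dweibull
  one3 <- blank[1, ]; one3$Md <- 250
  ld3 <- emissionLogDensity(one3, pf$spec, pf$params)
  ws <- weibullShapeScale(ep$Md$mean, ep$Md$sd)
  for (k in 1:3)
    expect_equal(ld3[1, k],
                 dweibull(250, ws$shape[k], ws$scale[k], log = TRUE),
                 tolerance = 1e-10)
})

test_that("negative stream values are rejected", {
  cfg <- simConfig(seed = 31)
  set.seed(31)
  sim <- simulateSteps(sample(1:3, 10, TRUE), cfg)
  sim$steps$Ms[3] <- -1
  pf0 <- paramsFromConfig(simulateSteps(sample(1:3, 10, TRUE), cfg)$steps, cfg)
  expect_error(emissionLogDensity(sim$steps, pf0$spec, pf0$params),
               "negative")
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  cfg <- simConfig(seed = 32)
  set.seed(32)
  for (rep in 1:6) {
    Tn <- sample(5:8, 1)
    G <- randomStochastic()
    sim <- simulateSteps(sample(1:3, Tn, TRUE), cfg)
    steps <- sim$steps
    if (rep %% 2 == 0) steps$Md[1] <- NA      # exercise marginalization
    pf <- paramsFromConfig(steps, cfg, Gamma = G)
    ld <- narhmm:::.emissionLogDens(pf$data, pf$spec, pf$params)
    delta <- stationaryDistribution(G)
    expect_equal(forwardLogLik(steps, pf$spec, pf$params),
                 enumLogLik(ld, G, delta), tolerance = 1e-8)
  }
})

test_that("a 1-state degenerate chain reduces to summed emission densities", {
  cfg <- simConfig(seed = 33)
  set.seed(33)
  sim <- simulateSteps(rep(2L, 10), cfg)
  pf <- paramsFromConfig(sim$steps, cfg)
  # concentrate all mass in state 2
  G <- matrix(c(0.001, 0.998, 0.001), 3, 3, byrow = TRUE)
  pf2 <- paramsFromConfig(sim$steps, cfg, Gamma = G)
  ld <- narhmm:::.emissionLogDens(pf2$data, pf2$spec, pf2$params)
  # with near-degenerate transitions the forward sum approaches state-2 path
  ll <- forwardLogLik(sim$steps, pf2$spec, pf2$params)
  expect_equal(ll, enumLogLik(ld, G, stationaryDistribution(G)),
               tolerance = 1e-8)
})

test_that("appending an all-missing step leaves the log-likelihood unchanged", {
  cfg <- simConfig(seed = 34)
  set.seed(34)
  sim <- simulateSteps(sample(1:3, 12, TRUE), cfg)
  pf <- paramsFromConfig(sim$steps, cfg)
  ll1 <- forwardLogLik(sim$steps, pf$spec, pf$params)
  extra <- sim$steps[12, ]
  extra[, c("Ms", "Tr", "Sf", "Md", "Rd", "Dp")] <- NA
  steps2 <- rbind(sim$steps, extra)
  ll2 <- forwardLogLik(steps2, pf$spec, pf$params)
  expect_equal(ll2, ll1, tolerance = 1e-10)
})

test_that("viterbi equals the exhaustive argmax on 5-step instances", {
  cfg <- simConfig(seed = 35)
  set.seed(35)
  for (rep in 1:5) {
    G <- randomStochastic()
    sim <- simulateSteps(sample(1:3, 5, TRUE), cfg)
    pf <- paramsFromConfig(sim$steps, cfg, Gamma = G)
    ld <- narhmm:::.emissionLogDens(pf$data, pf$spec, pf$params)
    delta <- stationaryDistribution(G)
    v <- viterbiPath(sim$steps, spec = pf$spec, params = pf$params)
    expect_equal(v, enumViterbi(ld, G, delta))
  }
})

test_that("uniform emissions and transitions decode all-1 by the tie rule", {
  ld <- matrix(0, 6, 3)
  tr <- array(1 / 3, c(3, 3, 6))
  delta <- matrix(1 / 3, 1, 3)
  v <- narhmm:::.hmmViterbiCpp(ld, tr, rep(1L, 6), delta)
  expect_equal(as.integer(v), rep(1L, 6))
})

test_that("viterbi path beats 1,000 random paths in joint likelihood", {
  cfg <- simConfig(seed = 36)
  set.seed(36)
  Tn <- 30
  G <- cfg$transition_spec
  sim <- simulateSteps(simulateStateSequence(cfg, Tn), cfg)
  pf <- paramsFromConfig(sim$steps, cfg)
  ld <- narhmm:::.emissionLogDens(pf$data, pf$spec, pf$params)
  delta <- stationaryDistribution(G)
  v <- viterbiPath(sim$steps, spec = pf$spec, params = pf$params)
  score <- function(p) {
    s <- log(delta[p[1]]) + ld[1, p[1]]
    for (t in 2:Tn) s <- s + log(G[p[t - 1], p[t]]) + ld[t, p[t]]
    s
  }
  sv <- score(v)
  for (i in 1:1000) expect_gte(sv, score(sample(1:3, Tn, TRUE)))
})

test_that("near-deterministic emissions recover the planted path", {
  cfg <- simConfig(seed = 37)
  # widely separated Md with tiny spread -> nearly deterministic labels
  cfg$state_emission_params$Md <- list(mean = c(50, 500, 1500),
                                       sd = c(5, 10, 20))
  set.seed(37)
  states <- simulateStateSequence(cfg, 800)
  sim <- simulateSteps(states, cfg)
  pf <- paramsFromConfig(sim$steps, cfg)
  v <- viterbiPath(sim$steps, spec = pf$spec, params = pf$params)
  expect_gte(mean(v == states), 0.99)
})

test_that("stationary probabilities: symmetry, normalization, eigen oracle", {
  G <- matrix(1 / 3, 3, 3)
  expect_equal(as.numeric(stationaryDistribution(G)), rep(1 / 3, 3),
               tolerance = 1e-12)
  set.seed(38)
  for (i in 1:20) {
    G <- randomStochastic()
    d <- stationaryDistribution(G)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_equal(as.numeric(d), eigenStationary(G), tolerance = 1e-10)
    expect_equal(as.numeric(d %*% G), as.numeric(d), tolerance = 1e-12)
  }
})

test_that("analytic gradient matches finite differences", {
  cfg <- simConfig(seed = 39)
  set.seed(39)
  sim <- simulateSteps(simulateStateSequence(cfg, 150), cfg)
  steps <- sim$steps
  steps$segment_id <- rep(c("a", "b"), each = 75)
  steps$Dp[c(3, 9)] <- 0
  steps$Ms[5] <- NA
  spec <- interceptOnlySpec()
  data <- narhmm:::prepareHMMData(steps, spec)
  tmpl <- narhmm:::hmmParamsTemplate(data, spec)
  set.seed(40)
  v <- narhmm:::packParams(narhmm:::.initParams(data, spec)) +
    rnorm(45, 0, 0.05)
  g <- narhmm:::.loglikGrad(v, data, spec, tmpl)
  f <- function(vv) {
    p <- narhmm:::unpackParams(vv, tmpl)
    ld <- narhmm:::.emissionLogDens(data, spec, p)
    narhmm:::.forwardFromParts(ld, data, p)$loglik
  }
  gn <- vapply(seq_along(v), function(j) {
    e <- 1e-6
    vp <- v; vp[j] <- vp[j] + e
    vm <- v; vm[j] <- vm[j] - e
    (f(vp) - f(vm)) / (2 * e)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-4)
})

test_that("fitting is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 41)
  set.seed(41)
  sim <- simulateSteps(simulateStateSequence(cfg, 400), cfg)
  f1 <- fitHMM(sim$steps, interceptOnlySpec(), n_starts = 1, seed = 2)
  f2 <- fitHMM(sim$steps, interceptOnlySpec(), n_starts = 1, seed = 2)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$states, f2$states)
})

test_that("self-consistency: refitting recovers the state-2 mean depth", {
  cfg <- simConfig(seed = 42)
  set.seed(42)
  sim <- simulateSteps(simulateStateSequence(cfg, 10000), cfg)
  fit <- fitHMM(sim$steps, interceptOnlySpec(), n_starts = 2, seed = 1)
  expect_lt(abs(fit$emissionMeans["Md", "state2"] - 220) / 220, 0.05)
  # relabeling worked: Md means increase with state index
  expect_true(all(diff(fit$emissionMeans["Md", 1:3]) > 0))
})

test_that("covariate-dependent emissions are recovered in direction", {
  # plant a positive bath effect on state-3 Md scale and check the sign
  cfg <- simConfig(seed = 43)
  set.seed(43)
  n <- 3000
  states <- simulateStateSequence(cfg, n)
  sim <- simulateSteps(states, cfg)
  steps <- sim$steps
  steps$bath <- rnorm(n, 1379, 300)
  bz <- (steps$bath - mean(steps$bath)) / sd(steps$bath)
  # regenerate state-3 Md with scale shifted by the covariate
  ws <- weibullShapeScale(331, 62)
  idx <- states == 3
  steps$Md[idx] <- rweibull(sum(idx), ws$shape,
                            ws$scale * exp(0.3 * bz[idx]))
  emis <- interceptOnlySpec()$emission
  emis$Md$formulas <- list(~1, ~1, ~bath)
  spec <- hmmSpec(emission = emis, transitionFormula = ~1)
  fit <- fitHMM(steps, spec, n_starts = 2, seed = 3)
  b_bath <- fit$params$emission$Md$beta2[[3]][2]
  expect_gt(b_bath, 0.15)
  expect_lt(abs(b_bath - 0.3), 0.15)
})

test_that("stationary curves respond to transition covariates as planted", {
  # increasing the wday coefficient for transitions into state 3 raises
  # delta_3 along the wday grid
  cfg <- simConfig(seed = 44)
  set.seed(44)
  n <- 1500
  wday <- round(seq(40, 220, length.out = n))
  base_beta <- narhmm:::.logitFromMatrix(cfg$transition_spec)
  beta <- rbind(base_beta, 0)
  wz <- (wday - mean(wday)) / sd(wday)
  # columns (1,2),(1,3),(2,1),(2,3),(3,1),(3,2): into-3 are cols 2 and 4
  beta[2, c(2, 4)] <- 0.8
  cfg$transition_spec <- list(formula = ~wday, beta = beta)
  states <- simulateStateSequence(cfg, n, covariates = data.frame(wday = wz))
  sim <- simulateSteps(states, cfg,
                       covariates = data.frame(bath = 1379, slope = 2,
                                               shore = 150, hour = 3,
                                               wday = wday))
  spec <- hmmSpec(emission = interceptOnlySpec()$emission,
                  transitionFormula = ~wday)
  fit <- fitHMM(sim$steps, spec, n_starts = 2, seed = 4)
  grid <- data.frame(wday = c(50, 120, 200))
  sp <- stationaryProbs(fit, grid)
  expect_true(all(diff(sp$delta_3) > 0))
  expect_equal(rowSums(sp[, c("delta_1", "delta_2", "delta_3")]),
               rep(1, 3), tolerance = 1e-9)
  # occupancy late in winter visibly exceeds early occupancy in truth too
  expect_gt(mean(states[wday > 180] == 3), mean(states[wday < 60] == 3))
})
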