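test_that("flat-bathymetry environment has zero slope everywhere", {
  env <- simulateEnvironment(c(600, 600), 10, seed = 1, profile = "flat")
  expect_true(all(env$slope == 0))
})

test_that("shore distance is zero exactly on 0-m cells", {
  env <- simulateEnvironment(c(800, 800), 10, seed = 2)
  expect_true(any(env$bathymetry == 0))          # coastal band exists
  expect_true(all(env$shore[env$bathymetry == 0] == 0))
  expect_true(all(env$shore[env$bathymetry > 0] > 0))
})

test_that("environment realizes a shelf-slope-basin structure", {
  env <- simulateEnvironment(c(1000, 1000), 10, seed = 3)
  b <- env$bathymetry
  expect_true(all(b >= 0))
  expect_gt(max(b), 1400)                        # basin
  expect_true(any(b > 450 & b < 750))            # shelf depths present
  expect_error(simulateEnvironment(c(5, 5), 10), "degenerate")
})

test_that("distance transform equals brute-force nearest-0-cell search", {
  env <- simulateEnvironment(c(500, 500), 5, seed = 1)   # 100x100 grid
  b <- env$bathymetry
  land <- which(b == 0, arr.ind = TRUE)
  # spot-check a deterministic sample of water cells against full scan
  water <- which(b > 0, arr.ind = TRUE)
  idx <- seq(1, nrow(water), length.out = 50)
  for (r in idx) {
    i <- water[r, 1]; j <- water[r, 2]
    d <- min(sqrt((land[, 1] - i)^2 + (land[, 2] - j)^2)) * env$res
    expect_equal(env$shore[i, j], d, tolerance = 1e-12)
  }
})

test_that("identity transition matrix freezes the chain in its start state", {
  cfg <- simConfig(transition_spec = {
    m <- diag(3); m  # absorbing everywhere
  }, seed = 1)
  set.seed(1)
  s <- suppressWarnings(simulateStateSequence(cfg, n_steps = 200))
  expect_length(unique(s), 1)
})

test_that("zero-row transition matrices are rejected", {
  m <- diag(3); m[2, ] <- 0
  cfg <- simConfig(seed = 1)
  cfg$transition_spec <- m
  expect_error(simulateStateSequence(cfg, n_steps = 10), "zero row")
})

test_that("long-run occupancy matches the stationary eigenvector", {
  cfg <- simConfig(seed = 1)
  delta <- eigenStationary(cfg$transition_spec)
  expect_equal(delta, c(0.2222, 0.3737, 0.4040), tolerance = 1e-3)
  set.seed(11)
  s <- simulateStateSequence(cfg, n_steps = 50000)
  occ <- tabulate(s, 3) / 50000
  expect_true(all(abs(occ - delta) < 0.01))
})

test_that("logit-intercept transition spec reproduces the fixed matrix", {
  G <- defaultTransitionMatrix()
  beta <- narhmm:::.logitFromMatrix(G)
  G2 <- transitionMatrices(beta, matrix(1, 5, 1))
  for (t in 1:5) expect_equal(G2[, , t], G, tolerance = 1e-12)
  cfg1 <- simConfig(seed = 1)
  cfg2 <- simConfig(seed = 1)
  cfg2$transition_spec <- list(formula = ~1, beta = beta)
  set.seed(4); s1 <- simulateStateSequence(cfg1, 500)
  set.seed(4)
  s2 <- simulateStateSequence(cfg2, 500,
                              covariates = data.frame(dummy = rep(1, 500)))
  expect_identical(s1, s2)
})

test_that("state-1 mean speed matches its published generating mean", {
  cfg <- simConfig(seed = 1)
  set.seed(21)
  sim <- simulateSteps(rep(1L, 10000), cfg)
  expect_equal(mean(sim$steps$Ms), 1902, tolerance = 0.02)
})

test_that("full zero-mass makes every Dp exactly zero", {
  cfg <- simConfig(seed = 1)
  cfg$state_emission_params$Dp$zeromass <- c(1, 1, 1)
  set.seed(5)
  sim <- simulateSteps(sample(1:3, 500, TRUE), cfg)
  expect_true(all(sim$steps$Dp == 0))
})

test_that("weibull stream sample mean matches lambda * Gamma(1 + 1/kappa)", {
  cfg <- simConfig(seed = 1)
  ws <- weibullShapeScale(cfg$state_emission_params$Md$mean[2],
                          cfg$state_emission_params$Md$sd[2])
  closed_form <- ws$scale * gamma(1 + 1 / ws$shape)
  set.seed(6)
  sim <- simulateSteps(rep(2L, 10000), cfg)
  mc_se <- cfg$state_emission_params$Md$sd[2] / sqrt(10000)
  expect_lt(abs(mean(sim$steps$Md) - closed_form), 4 * mc_se)
})

test_that("stream marginals pass two-sample tests against direct draws", {
  cfg <- simConfig(seed = 1)
  ep <- cfg$state_emission_params
  set.seed(7)
  sim <- simulateSteps(rep(3L, 10000), cfg)
  p <- gammaShapeRate(ep$Sf$mean[3], ep$Sf$sd[3])
  ref <- rgamma(10000, p$shape, p$rate)
  expect_gt(suppressWarnings(ks.test(sim$steps$Sf, ref))$p.value, 0.01)
  w <- weibullShapeScale(ep$Md$mean[3], ep$Md$sd[3])
  refw <- rweibull(10000, w$shape, w$scale)
  expect_gt(suppressWarnings(ks.test(sim$steps$Md, refw))$p.value, 0.01)
  # zero-inflated Dp: zero fraction and positive part separately
  expect_lt(abs(mean(sim$steps$Dp == 0) - ep$Dp$zeromass[3]), 0.01)
})

test_that("the generator is fully deterministic under a fixed seed", {
  a <- simulateDataset(simConfig(n_animals = 2, n_steps_per_animal = 60,
                                 seed = 9))
  b <- simulateDataset(simConfig(n_animals = 2, n_steps_per_animal = 60,
                                 seed = 9))
  expect_identical(a$locations, b$locations)
  expect_identical(a$divebins, b$divebins)
  expect_identical(a$steps, b$steps)
})

test_that("degradation without error/dropout returns true positions", {
  cfg <- simConfig(n_steps_per_animal = 40, seed = 10,
                   argos_smaj_km = 0, argos_smin_km = 0, dropout_prob = 0)
  cfg$duty_cycle_days <- 1
  env <- simulateEnvironment(seed = 11)
  set.seed(12)
  states <- simulateStateSequence(cfg, 40)
  sim <- simulateSteps(states, cfg, env = env)
  deg <- degradeToArgos(sim, cfg, env)
  xy <- projectAEQD(deg$locations$lon, deg$locations$lat, env$center)
  truth <- sim$truth$fine[match(deg$locations$timestamp, sim$truth$fine$time), ]
  expect_equal(xy$x, truth$x, tolerance = 1e-6)
  expect_equal(xy$y, truth$y, tolerance = 1e-6)
})

test_that("every emitted TAD histogram sums to 100% with integer DMD", {
  cfg <- simConfig(n_steps_per_animal = 60, seed = 13)
  env <- simulateEnvironment(seed = 13)
  set.seed(13)
  sim <- simulateSteps(simulateStateSequence(cfg, 60), cfg, env = env)
  deg <- degradeToArgos(sim, cfg, env)
  tad <- as.matrix(deg$divebins[, grep("^tad_", names(deg$divebins))])
  dmd <- as.matrix(deg$divebins[, grep("^dmd_", names(deg$divebins))])
  expect_gt(nrow(tad), 0)
  expect_true(all(abs(rowSums(tad) - 100) < 1e-9))
  expect_true(all(dmd >= 0 & dmd == round(dmd)))
})

test_that("hand-built depth series bins 50/50 into the expected bins", {
  # 3 h at 10 m and 3 h at 450 m
  depths <- c(rep(10, 36), rep(450, 36))
  for (prog in c("2009", "2010+")) {
    edges <- diveBinEdges(prog)
    hb <- binDepthSeries(depths, prog)
    b10 <- findInterval(10, edges)
    b450 <- findInterval(450, edges)
    expect_equal(hb$tad[b10], 50)
    expect_equal(hb$tad[b450], 50)
    expect_equal(sum(hb$tad), 100)
  }
})

test_that("unknown tag dialect is rejected", {
  expect_error(diveBinEdges("2013"), "arg")
  cfg <- simConfig(seed = 1)
  cfg$prog <- "bogus"
  env <- simulateEnvironment(seed = 1)
  set.seed(1)
  sim <- simulateSteps(simulateStateSequence(cfg, 20), cfg, env = env)
  expect_error(degradeToArgos(sim, cfg, env), "prog")
})

test_that("states outside 1..3 are rejected", {
  cfg <- simConfig(seed = 1)
  expect_error(simulateSteps(c(1L, 4L), cfg))
})
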