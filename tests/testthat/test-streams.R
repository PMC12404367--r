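test_that("tortuosity: straight, square, and degenerate paths", {
  expect_equal(computeTortuosity(c(0, 1, 2, 3), c(0, 0, 0, 0)), 0)
  expect_equal(computeTortuosity(c(0, 1, 1, 0), c(0, 0, 1, 1)), 2)
  expect_message(res <- computeTortuosity(c(0, 1, 1, 0), c(0, 0, 1, 0)),
                 "closed loop")
  expect_true(is.na(res))
})

test_that("tortuosity is non-negative on random paths", {
  set.seed(20)
  for (i in 1:50) {
    x <- rnorm(4); y <- rnorm(4)
    tr <- suppressMessages(computeTortuosity(x, y))
    if (!is.na(tr)) expect_gte(tr, -1e-12)
  }
})

test_that("a revisiting path is more tortuous than the direct one", {
  direct <- computeTortuosity(c(0, 1, 2, 3), c(0, 0.1, -0.1, 0))
  revisit <- computeTortuosity(c(0, 2, 1, 3), c(0, 0.1, -0.1, 0))
  expect_gt(revisit, direct)
})

test_that("mean speed handles stationary, known, and single-point cases", {
  t0 <- as.POSIXct("2010-11-01 03:00:00", tz = "UTC")
  times <- t0 + c(0, 2, 4) * 3600
  expect_equal(computeMeanSpeed(c(1, 1, 1), c(2, 2, 2), times), 0)
  # three positions 2 h apart, each 2,000 m along x -> 1000 m/hr
  expect_equal(computeMeanSpeed(c(0, 2, 4), c(0, 0, 0), times), 1000)
  expect_true(is.na(computeMeanSpeed(1, 1, t0)))
})

test_that("path speed is at least straight-line displacement speed", {
  set.seed(21)
  t0 <- as.POSIXct("2010-11-01 03:00:00", tz = "UTC")
  times <- t0 + seq(0, 6, by = 2) * 3600
  for (i in 1:20) {
    x <- cumsum(rnorm(4)); y <- cumsum(rnorm(4))
    ms <- computeMeanSpeed(x, y, times)
    straight <- sqrt((x[4] - x[1])^2 + (y[4] - y[1])^2) * 1000 / 6
    expect_gte(ms, straight - 1e-9)
  }
})

test_that("all-shallow TAD gives Sf = 100 and Dp = 0", {
  for (prog in c("2009", "2010+")) {
    nb <- length(diveBinEdges(prog)) - 1
    tad <- c(100, rep(0, nb - 1))
    ds <- computeDiveStreams(tad, prog, bath = 1000)
    expect_equal(ds$Sf, 100)
    expect_equal(ds$Dp, 0)
    expect_true(is.na(ds$Md))  # no sub-surface mass to average
  }
})

test_that("mean depth equals the TAD-weighted midpoint oracle", {
  prog <- "2010+"
  edges <- diveBinEdges(prog)
  mids <- diveBinMidpoints(prog)
  nb <- length(edges) - 1
  iA <- findInterval(120, edges)   # a mid-depth bin
  iB <- findInterval(700, edges)   # a deep bin
  tad <- rep(0, nb); tad[iA] <- 40; tad[iB] <- 60
  ds <- computeDiveStreams(tad, prog, bath = 1400)
  expect_equal(ds$Md, 0.4 * mids[iA] + 0.6 * mids[iB])
  expect_equal(ds$Rd, ds$Md / 1400)
  expect_equal(ds$Dp, 60)          # the 600-800 bin is fully below 400 m
})

test_that("the two dialects bin one depth series differently", {
  set.seed(22)
  depths <- c(runif(100, 0, 5), runif(150, 50, 380), runif(110, 420, 980))
  r09 <- binDepthSeries(depths, "2009")
  r10 <- binDepthSeries(depths, "2010+")
  ds09 <- computeDiveStreams(r09$tad, "2009", bath = 1200)
  ds10 <- computeDiveStreams(r10$tad, "2010+", bath = 1200)
  expect_false(isTRUE(all.equal(ds09$Md, ds10$Md)))
  # boundary streams agree because 6 m and 400 m are edges in both dialects
  expect_equal(ds09$Sf, ds10$Sf, tolerance = 1e-9)
  expect_equal(ds09$Dp, ds10$Dp, tolerance = 1e-9)
})

test_that("wrong-length TAD vector is rejected as a dialect mismatch", {
  expect_error(computeDiveStreams(rep(10, 10), "2010+", 1000), "expects")
})

test_that("Sf + Dp never exceeds 100 and Rd lies in (0, 1]", {
  set.seed(23)
  for (i in 1:30) {
    prog <- sample(c("2009", "2010+"), 1)
    nb <- length(diveBinEdges(prog)) - 1
    tad <- rgamma(nb, 0.5); tad <- tad / sum(tad) * 100
    ds <- computeDiveStreams(tad, prog, bath = runif(1, 300, 2000))
    expect_lte(ds$Sf + ds$Dp, 100 + 1e-9)
    if (!is.na(ds$Rd)) {
      expect_gt(ds$Rd, 0)
      expect_lte(ds$Rd, 1)
    }
  }
})

test_that("covariates on a constant raster return that constant", {
  env <- simulateEnvironment(c(600, 600), 10, seed = 1, profile = "flat")
  t0 <- as.POSIXct("2009-11-07 00:00:00", tz = "UTC")
  cov <- extractCovariates(c(100, 300), c(100, 300), rep(t0, 2), env)
  expect_equal(cov$bath, c(1000, 1000))
  expect_equal(cov$slope, c(0, 0))
})

test_that("winter day arithmetic counts days since September 1", {
  t0 <- as.POSIXct("2009-11-07 00:00:00", tz = "UTC")
  env <- simulateEnvironment(c(300, 300), 10, seed = 1, profile = "flat")
  cov <- extractCovariates(150, 150, t0, env)
  expect_equal(cov$wday, 67)
  expect_equal(cov$hour, 20)           # 00:00 UTC is 20:00 local (UTC-4)
  cov2 <- extractCovariates(150, 150,
                            as.POSIXct("2010-03-01 12:00:00", tz = "UTC"), env)
  expect_equal(cov2$wday, 181)         # season start year rolls back to 2009
})

test_that("buffer maximum equals an exhaustive scan within 20 km", {
  env <- simulateEnvironment(c(500, 500), 10, seed = 24)
  set.seed(24)
  xs <- runif(5, 150, 450); ys <- runif(5, 50, 450)
  t0 <- as.POSIXct("2010-12-01 09:00:00", tz = "UTC")
  cov <- extractCovariates(xs, ys, rep(t0, 5), env)
  cx <- env$origin[1] + (seq_len(ncol(env$bathymetry)) - 0.5) * env$res
  cy <- env$origin[2] + (seq_len(nrow(env$bathymetry)) - 0.5) * env$res
  for (i in 1:5) {
    d2 <- outer((cy - ys[i])^2, (cx - xs[i])^2, `+`)
    sel <- d2 <= 20^2
    expect_equal(cov$bath[i], max(env$bathymetry[sel]))
    expect_equal(cov$slope[i], mean(env$slope[sel]))
  }
})

test_that("positions outside the raster extent are rejected", {
  env <- simulateEnvironment(c(300, 300), 10, seed = 1)
  t0 <- as.POSIXct("2010-12-01 09:00:00", tz = "UTC")
  expect_error(extractCovariates(500, 100, t0, env), "outside")
})

test_that("buildSteps assembles aligned windows with streams and covariates", {
  cfg <- simConfig(n_steps_per_animal = 80, seed = 25, dropout_prob = 0)
  cfg$duty_cycle_days <- 1
  env <- simulateEnvironment(seed = 25)
  set.seed(25)
  sim <- simulateSteps(simulateStateSequence(cfg, 80), cfg, env = env)
  deg <- degradeToArgos(sim, cfg, env)
  fine <- sim$truth$fine
  pred <- data.frame(animal_id = "sim01", segment_id = "s1",
                     time = fine$time, x = fine$x, y = fine$y)
  steps <- buildSteps(pred, deg$divebins, env, prog = cfg$prog)
  expect_gt(nrow(steps), 40)
  expect_true(all(format(steps$step_time, "%H") %in% c("03", "09", "15", "21")))
  # last three steps of the segment have missing tortuosity
  expect_true(all(is.na(tail(steps$Tr, 3))))
  expect_true(all(steps$Sf >= 0 & steps$Sf <= 100, na.rm = TRUE))
  expect_true(all(steps$Md <= steps$bath, na.rm = TRUE))
  # mean speed of rebuilt steps correlates with the generating stream
  common <- match(steps$step_time, sim$steps$step_time)
  expect_gt(cor(steps$Ms, sim$steps$Ms[common], use = "complete"), 0.8)
})
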