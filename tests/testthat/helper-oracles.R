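# Independent oracles used across tests. These deliberately use brute-force
# formulations (path enumeration, exhaustive scans, dense Gaussian algebra)
# rather than the package's recursions.

# log-likelihood of an HMM by summing over every state path
enumLogLik <- function(ldens, Gamma, delta) {
  Tn <- nrow(ldens); K <- ncol(ldens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  scores <- apply(paths, 1, function(p) {
    s <- log(delta[p[1]]) + ldens[1, p[1]]
    if (Tn > 1) for (t in 2:Tn) s <- s + log(Gamma[p[t - 1], p[t]]) + ldens[t, p[t]]
    s
  })
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

# best path by the same enumeration
enumViterbi <- function(ldens, Gamma, delta) {
  Tn <- nrow(ldens); K <- ncol(ldens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  scores <- apply(paths, 1, function(p) {
    s <- log(delta[p[1]]) + ldens[1, p[1]]
    if (Tn > 1) for (t in 2:Tn) s <- s + log(Gamma[p[t - 1], p[t]]) + ldens[t, p[t]]
    s
  })
  as.integer(paths[which.max(scores), ])
}

# stationary distribution as the leading left eigenvector
eigenStationary <- function(Gamma) {
  ev <- eigen(t(Gamma))
  i <- which.min(abs(ev$values - 1))
  d <- Re(ev$vectors[, i])
  d / sum(d)
}

# a random 3x3 row-stochastic matrix with strictly positive entries
randomStochastic <- function() {
  m <- matrix(stats::rgamma(9, 2, 1) + 0.05, 3, 3)
  m / rowSums(m)
}

# small step table drawn from the generator at fixed covariates
makeSteps <- function(n, seed = 1, config = simConfig(seed = seed)) {
  set.seed(seed)
  states <- simulateStateSequence(config, n_steps = n)
  sim <- simulateSteps(states, config)
  list(steps = sim$steps, states = states, config = config)
}

# dense-Gaussian CTCRW oracle: joint distribution of all states at `times`
# conditioned on the 2-D observations, replicating the filter's prior
ctcrwGaussianOracle <- function(times, obs, Rlist, beta, sigma,
                                diffuse_pos = 1e4) {
  n <- length(times)
  svel <- sigma^2 / (2 * beta)
  first <- which(!is.na(obs[, 1]))[1]
  m <- rep(0, 4 * n)
  m[(first - 1) * 4 + 1] <- obs[first, 1]
  m[(first - 1) * 4 + 3] <- obs[first, 2]
  P1 <- diag(c(diffuse_pos, svel, diffuse_pos, svel))
  # propagate marginal means/covs and transition products
  Phis <- vector("list", n); Ps <- vector("list", n)
  Ps[[1]] <- P1
  ms <- matrix(0, n, 4); ms[1, ] <- m[1:4]
  for (i in 2:n) {
    M <- narhmm:::.iouMats(beta, sigma, times[i] - times[i - 1])
    Phis[[i]] <- M$T4
    ms[i, ] <- as.numeric(M$T4 %*% ms[i - 1, ])
    Ps[[i]] <- M$T4 %*% Ps[[i - 1]] %*% t(M$T4) + M$Q4
  }
  Sig <- matrix(0, 4 * n, 4 * n)
  for (i in 1:n) {
    ii <- (i - 1) * 4 + 1:4
    Sig[ii, ii] <- Ps[[i]]
    if (i < n) {
      A <- diag(4)
      for (j in (i + 1):n) {
        A <- Phis[[j]] %*% A
        jj <- (j - 1) * 4 + 1:4
        Sig[jj, ii] <- A %*% Ps[[i]]
        Sig[ii, jj] <- t(Sig[jj, ii])
      }
    }
  }
  mu <- as.numeric(t(ms))
  oi <- which(!is.na(obs[, 1]))
  H <- matrix(0, 2 * length(oi), 4 * n)
  Rbig <- matrix(0, 2 * length(oi), 2 * length(oi))
  y <- numeric(2 * length(oi))
  for (k in seq_along(oi)) {
    r <- (k - 1) * 2 + 1:2
    H[r[1], (oi[k] - 1) * 4 + 1] <- 1
    H[r[2], (oi[k] - 1) * 4 + 3] <- 1
    Rbig[r, r] <- Rlist[[oi[k]]]
    y[r] <- obs[oi[k], ]
  }
  S <- H %*% Sig %*% t(H) + Rbig
  Kg <- Sig %*% t(H) %*% solve(S)
  post_mean <- mu + as.numeric(Kg %*% (y - H %*% mu))
  post_cov <- Sig - Kg %*% H %*% Sig
  list(mean = matrix(post_mean, n, 4, byrow = TRUE), cov = post_cov)
}

# small helper: intercept-only params object built from generator values
paramsFromConfig <- function(steps, cfg, Gamma = cfg$transition_spec) {
  spec <- interceptOnlySpec()
  data <- narhmm:::prepareHMMData(steps, spec)
  p <- narhmm:::hmmParamsTemplate(data, spec)
  ep <- cfg$state_emission_params
  for (s in c("Ms", "Tr", "Sf", "Dp")) {
    for (k in 1:3) {
      p$emission[[s]]$beta1[[k]][1] <- log(ep[[s]]$mean[k])
      p$emission[[s]]$beta2[[k]][1] <- log(ep[[s]]$sd[k])
    }
  }
  for (s in c("Md", "Rd")) {
    ws <- weibullShapeScale(ep[[s]]$mean, ep[[s]]$sd)
    for (k in 1:3) {
      p$emission[[s]]$beta1[[k]][1] <- log(ws$shape[k])
      p$emission[[s]]$beta2[[k]][1] <- log(ws$scale[k])
    }
  }
  p$emission$Dp$zeta <- qlogis(pmin(pmax(ep$Dp$zeromass, 1e-4), 1 - 1e-4))
  p$trans_beta <- narhmm:::.logitFromMatrix(Gamma)
  list(params = p, spec = spec, data = data)
}

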