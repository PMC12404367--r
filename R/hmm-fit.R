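# ---- parameter plumbing -----------------------------------------------------

# skeleton parameter object with zero coefficients
hmmParamsTemplate <- function(data, spec) {
  K <- data$K
  emission <- list()
  for (s in names(spec$emission)) {
    p <- lapply(data$Xe[[s]], ncol)
    emission[[s]] <- list(
      beta1 = lapply(p, numeric),
      beta2 = lapply(p, numeric),
      zeta = if (isTRUE(spec$emission[[s]]$zeromass)) numeric(K) else NULL)
  }
  list(emission = emission,
       trans_beta = matrix(0, ncol(data$Xt), K * (K - 1)))
}

packParams <- function(params) {
  v <- numeric(0)
  for (s in names(params$emission)) {
    e <- params$emission[[s]]
    v <- c(v, unlist(e$beta1), unlist(e$beta2), e$zeta)
  }
  c(v, as.numeric(params$trans_beta))
}

unpackParams <- function(v, template) {
  pos <- 0L
  take <- function(n) {
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  out <- template
  for (s in names(template$emission)) {
    e <- template$emission[[s]]
    for (k in seq_along(e$beta1)) out$emission[[s]]$beta1[[k]] <- take(length(e$beta1[[k]]))
    for (k in seq_along(e$beta2)) out$emission[[s]]$beta2[[k]] <- take(length(e$beta2[[k]]))
    if (!is.null(e$zeta)) out$emission[[s]]$zeta <- take(length(e$zeta))
  }
  nt <- length(template$trans_beta)
  out$trans_beta <- matrix(take(nt), nrow(template$trans_beta),
                           ncol(template$trans_beta))
  if (pos != length(v)) stop("parameter vector length mismatch")
  out
}

# ---- emission densities -----------------------------------------------------

# T x K matrix of summed per-stream emission log-densities; missing stream
# values contribute 0 (marginalized out)
.emissionLogDens <- function(data, spec, params, keep_stream = NULL) {
  Tn <- nrow(data$obs); K <- data$K
  ld <- matrix(0, Tn, K)
  streams <- if (is.null(keep_stream)) names(spec$emission) else keep_stream
  for (s in streams) {
    x <- data$obs[, s]
    ok <- !is.na(x)
    if (!any(ok)) next
    e <- spec$emission[[s]]
    pe <- params$emission[[s]]
    for (k in seq_len(K)) {
      X <- data$Xe[[s]][[k]]
      par1 <- exp(as.numeric(X[ok, , drop = FALSE] %*% pe$beta1[[k]]))
      par2 <- exp(as.numeric(X[ok, , drop = FALSE] %*% pe$beta2[[k]]))
      xi <- x[ok]
      if (e$dist == "gamma") {
        shp <- (par1 / par2)^2
        rte <- par1 / par2^2
        li <- stats::dgamma(xi, shape = shp, rate = rte, log = TRUE)
        if (isTRUE(e$zeromass)) {
          z <- stats::plogis(pe$zeta[k])
          li <- ifelse(xi == 0, log(z), log1p(-z) + li)
        }
      } else {
        li <- stats::dweibull(xi, shape = par1, scale = par2, log = TRUE)
      }
      ld[ok, k] <- ld[ok, k] + li
    }
  }
  ld
}

#' Per-step emission log-densities
#'
#' Sum over the available streams of each state's emission log-density:
#' gamma (mean/SD converted to shape/rate) for Ms, Tr, Sf and the positive
#' part of Dp, Weibull (shape/scale) for Md and Rd. A zero Dp contributes
#' `log z_state`, a positive Dp `log(1 - z_state)` plus the gamma density;
#' missing streams contribute 0 so steps with partial data are marginalized
#' rather than dropped.
#'
#' @param steps StepRecord data.frame.
#' @param spec An [hmmSpec()].
#' @param params Parameter object (as in a fitted model's `$params`).
#' @param scale Covariate scaling to reuse (default: derived from `steps`).
#' @return Numeric matrix, steps by states.
#' @export
emissionLogDensity <- function(steps, spec, params, scale = NULL) {
  data <- prepareHMMData(steps, spec, scale)
  .emissionLogDens(data, spec, params)
}

# ---- forward likelihood -----------------------------------------------------

# build transition array and per-segment initial (stationary) distributions
.transParts <- function(data, params) {
  tr <- transitionMatrices(params$trans_beta, data$Xt, data$K)
  firsts <- which(!duplicated(data$seg))
  delta <- t(vapply(firsts, function(i) {
    d <- stationaryDistribution(tr[, , i])
    pmax(as.numeric(d), 1e-12)
  }, numeric(data$K)))
  delta <- delta / rowSums(delta)
  list(tr = tr, delta = delta)
}

.forwardFromParts <- function(ldens, data, params, want_post = FALSE) {
  tp <- .transParts(data, params)
  .hmmForwardCpp(ldens, tp$tr, as.integer(data$seg), tp$delta, want_post)
}

#' Forward log-likelihood of the HMM
#'
#' Numerically-stabilized forward recursion, summed over track segments as
#' independent blocks; each segment's initial distribution is the
#' stationary distribution of the transition matrix at its first step's
#' covariates.
#'
#' @inheritParams emissionLogDensity
#' @return The total log-likelihood (scalar).
#' @export
forwardLogLik <- function(steps, spec, params, scale = NULL) {
  data <- prepareHMMData(steps, spec, scale)
  ld <- .emissionLogDens(data, spec, params)
  bad <- !is.finite(rowSums(ld))
  if (any(bad))
    stop("non-finite emission density at step(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  .forwardFromParts(ld, data, params)$loglik
}

# ---- analytic emission-score, numeric transition-score gradient -------------

# gradient of the log-likelihood w.r.t. the packed parameter vector;
# emission blocks use the Fisher identity (posterior-weighted complete-data
# scores), the transition block central differences on the cheap forward
# pass with the emission densities held fixed
.loglikGrad <- function(v, data, spec, template) {
  params <- unpackParams(v, template)
  ld <- .emissionLogDens(data, spec, params)
  fw <- .forwardFromParts(ld, data, params, want_post = TRUE)
  if (!is.finite(fw$loglik)) return(rep(NA_real_, length(v)))
  post <- fw$post
  K <- data$K
  g <- numeric(0)
  for (s in names(spec$emission)) {
    e <- spec$emission[[s]]
    pe <- params$emission[[s]]
    x <- data$obs[, s]
    ok <- !is.na(x)
    g1 <- list(); g2 <- list(); gz <- NULL
    for (k in seq_len(K)) {
      X <- data$Xe[[s]][[k]]
      if (!any(ok)) {
        g1[[k]] <- numeric(ncol(X)); g2[[k]] <- numeric(ncol(X))
        next
      }
      Xo <- X[ok, , drop = FALSE]
      par1 <- exp(as.numeric(Xo %*% pe$beta1[[k]]))
      par2 <- exp(as.numeric(Xo %*% pe$beta2[[k]]))
      xi <- x[ok]
      w <- post[ok, k]
      if (e$dist == "gamma") {
        pos <- if (isTRUE(e$zeromass)) xi > 0 else rep(TRUE, length(xi))
        a <- (par1 / par2)^2
        r <- par1 / par2^2
        A <- a * (log(r) - digamma(a) + ifelse(pos, log(pmax(xi, 1e-300)), 0))
        B <- a - r * xi
        d1 <- ifelse(pos, 2 * A + B, 0)
        d2 <- ifelse(pos, -2 * A - 2 * B, 0)
      } else {
        tt <- log(xi / par2)
        u <- (xi / par2)^par1
        d1 <- 1 + par1 * tt * (1 - u)
        d2 <- par1 * (u - 1)
      }
      g1[[k]] <- as.numeric(crossprod(Xo, w * d1))
      g2[[k]] <- as.numeric(crossprod(Xo, w * d2))
    }
    if (!is.null(pe$zeta)) {
      gz <- vapply(seq_len(K), function(k) {
        z <- stats::plogis(pe$zeta[k])
        xi <- x[ok]
        dz <- ifelse(xi == 0, 1 - z, -z)
        sum(post[ok, k] * dz)
      }, numeric(1))
    }
    g <- c(g, unlist(g1), unlist(g2), gz)
  }
  # transition block: central differences on the forward pass only
  nt <- length(template$trans_beta)
  base_len <- length(g)
  gt <- numeric(nt)
  eps <- 1e-5
  for (j in seq_len(nt)) {
    vp <- v; vp[base_len + j] <- vp[base_len + j] + eps
    vm <- v; vm[base_len + j] <- vm[base_len + j] - eps
    lp <- .forwardFromParts(ld, data, unpackParams(vp, template))$loglik
    lm <- .forwardFromParts(ld, data, unpackParams(vm, template))$loglik
    gt[j] <- (lp - lm) / (2 * eps)
  }
  c(g, gt)
}

# ---- initialization ---------------------------------------------------------

# quantile-based state seeding: states ordered by Md tertiles, per-state
# moments converted to working-scale intercepts
.initParams <- function(data, spec) {
  K <- data$K
  template <- hmmParamsTemplate(data, spec)
  md <- data$obs[, "Md"]
  if (all(is.na(md))) md <- data$obs[, 1]
  qs <- stats::quantile(md, probs = seq_len(K - 1) / K, na.rm = TRUE)
  cls <- findInterval(md, qs) + 1L
  cls[is.na(cls)] <- sample.int(K, sum(is.na(cls)), replace = TRUE)
  params <- template
  for (s in names(spec$emission)) {
    e <- spec$emission[[s]]
    x <- data$obs[, s]
    for (k in seq_len(K)) {
      xi <- x[cls == k & !is.na(x)]
      if (isTRUE(e$zeromass)) {
        zfrac <- mean(xi == 0)
        params$emission[[s]]$zeta[k] <-
          stats::qlogis(min(max(zfrac, 0.02), 0.95))
        xi <- xi[xi > 0]
      }
      m <- mean(xi); sd_ <- stats::sd(xi)
      if (!is.finite(m) || m <= 0) m <- mean(x[x > 0], na.rm = TRUE)
      if (!is.finite(sd_) || sd_ <= 0) sd_ <- m
      if (e$dist == "gamma") {
        params$emission[[s]]$beta1[[k]][1] <- log(m)
        params$emission[[s]]$beta2[[k]][1] <- log(sd_)
      } else {
        ws <- weibullShapeScale(m, sd_)
        params$emission[[s]]$beta1[[k]][1] <- log(ws$shape)
        params$emission[[s]]$beta2[[k]][1] <- log(ws$scale)
      }
    }
  }
  Gamma0 <- diag(0.7, K) + (1 - 0.7) / K
  params$trans_beta[1, ] <- .logitFromMatrix(Gamma0)
  params
}

# ---- fitting ----------------------------------------------------------------

#' Fit the behavioural HMM by direct likelihood maximization
#'
#' Maximizes the forward log-likelihood over all emission and transition
#' coefficients on the working (log / logit) scale with a quasi-Newton
#' optimizer, from `n_starts` initializations (the first from
#' quantile-based state seeding on mean depth, the rest perturbed). The
#' best solution is relabeled so the state-specific mean of Md increases
#' with the state index (1 = surface, 2 = pelagic, 3 = deep), then decoded.
#'
#' @param steps StepRecord data.frame (with `segment_id` for gap-split
#'   tracks; covariates required by the spec formulas must be complete).
#' @param spec An [hmmSpec()]; default the published model structure.
#' @param n_starts Number of optimizer starts (default 10).
#' @param seed Seed for start perturbation.
#' @param maxit Iteration cap per start.
#' @param hessian Reserved; currently unused.
#' @return An object of class `hmmFit` with elements `params`, `loglik`,
#'   `npar`, `aic`, `post` (per-step state probabilities), `states`
#'   (Viterbi path), `spec`, `covScale`, `emissionMeans` (natural-scale
#'   per-state means at reference covariates) and per-start diagnostics.
#' @export
fitHMM <- function(steps, spec = hmmSpec(), n_starts = 10, seed = 1L,
                   maxit = 400, hessian = FALSE) {
  if (nrow(steps) < 50) stop("need at least 50 steps to fit the HMM")
  data <- prepareHMMData(steps, spec)
  template <- hmmParamsTemplate(data, spec)
  set.seed(seed)
  p0 <- .initParams(data, spec)
  v0 <- packParams(p0)

  # optimizers probe extreme working values; NaN densities there are
  # rejected with a large objective rather than surfaced as warnings
  negll <- function(v) suppressWarnings({
    params <- unpackParams(v, template)
    ld <- .emissionLogDens(data, spec, params)
    if (any(is.na(ld))) return(1e10)
    ll <- .forwardFromParts(ld, data, params)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  })
  neggr <- function(v) suppressWarnings({
    g <- .loglikGrad(v, data, spec, template)
    if (all(is.finite(g))) -g else rep(0, length(v))
  })

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    vs <- if (s == 1) v0 else v0 + stats::rnorm(length(v0), 0, 0.25)
    runs[[s]] <- tryCatch(
      stats::optim(vs, negll, neggr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(vals)))
    stop("all optimizer starts failed; per-start diagnostics attached",
         call. = FALSE)
  best <- runs[[which.min(vals)]]
  params <- unpackParams(best$par, template)

  params <- .relabelByMd(params, data, spec)
  ld <- .emissionLogDens(data, spec, params)
  fw <- .forwardFromParts(ld, data, params, want_post = TRUE)
  tp <- .transParts(data, params)
  vit <- .hmmViterbiCpp(ld, tp$tr, as.integer(data$seg), tp$delta)

  structure(list(
    params = params, loglik = -best$value, npar = length(best$par),
    aic = 2 * best$value + 2 * length(best$par),
    post = fw$post, states = as.integer(vit),
    spec = spec, covScale = data$covScale,
    emissionMeans = .emissionMeansAtRef(params, data, spec),
    convergence = best$convergence,
    start_values = vals, n_steps = nrow(steps)
  ), class = "hmmFit")
}

# per-state natural-scale emission means at the reference design row
# (standardized covariates at 0, prog at reference level)
.emissionMeansAtRef <- function(params, data, spec) {
  K <- data$K
  out <- list()
  for (s in names(spec$emission)) {
    e <- spec$emission[[s]]
    pe <- params$emission[[s]]
    row <- vapply(seq_len(K), function(k) {
      X <- data$Xe[[s]][[k]]
      xref <- rep(0, ncol(X))
      xref[colnames(X) == "(Intercept)"] <- 1
      p1 <- exp(sum(xref * pe$beta1[[k]]))
      p2 <- exp(sum(xref * pe$beta2[[k]]))
      if (e$dist == "gamma") p1 else p2 * gamma(1 + 1 / p1)
    }, numeric(1))
    out[[s]] <- row
  }
  res <- do.call(rbind, out)
  colnames(res) <- paste0("state", seq_len(data$K))
  if (!is.null(params$emission$Dp$zeta))
    res <- rbind(res, zeromass_Dp = stats::plogis(params$emission$Dp$zeta))
  res
}

# permute state labels so the reference-covariate Md mean is increasing
.relabelByMd <- function(params, data, spec) {
  K <- data$K
  md <- .emissionMeansAtRef(params, data, spec)["Md", seq_len(K)]
  perm <- order(md)                     # perm[new] = old
  if (all(perm == seq_len(K))) return(params)
  out <- params
  for (s in names(params$emission)) {
    out$emission[[s]]$beta1 <- params$emission[[s]]$beta1[perm]
    out$emission[[s]]$beta2 <- params$emission[[s]]$beta2[perm]
    if (!is.null(params$emission[[s]]$zeta))
      out$emission[[s]]$zeta <- params$emission[[s]]$zeta[perm]
  }
  # transition columns are ordered (i,j) over off-diagonals; map old pair
  # (perm[i], perm[j]) -> new pair (i, j)
  pairs <- which(matrix(TRUE, K, K) & !diag(K), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  colOf <- function(i, j) which(pairs[, 1] == i & pairs[, 2] == j)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    out$trans_beta[, colOf(i, j)] <-
      params$trans_beta[, colOf(perm[i], perm[j])]
  }
  out
}

#' @export
print.hmmFit <- function(x, ...) {
  cat("3-state HMM fit:", x$n_steps, "steps;", x$npar,
      "parameters; logLik =", round(x$loglik, 2),
      "; AIC =", round(x$aic, 2), "\n")
  cat("State means at reference covariates:\n")
  print(round(x$emissionMeans, 3))
  tb <- table(factor(x$states, levels = seq_len(x$spec$nbStates)))
  cat("Decoded time budget (%):",
      paste(sprintf("%s: %.1f", names(tb), 100 * tb / sum(tb)),
            collapse = ", "), "\n")
  invisible(x)
}

# ---- decoding and stationary curves ----------------------------------------

#' Viterbi decoding
#'
#' Most likely state sequence by the max-product dynamic program, run per
#' segment; ties break toward the lower state index.
#'
#' @param steps StepRecord data.frame, or omitted when `fit` carries its
#'   decoding already.
#' @param fit An [fitHMM()] object (or a params object plus `spec`).
#' @param spec,params,scale Alternative raw interface.
#' @return Integer state path.
#' @export
viterbiPath <- function(steps, fit = NULL, spec = NULL, params = NULL,
                        scale = NULL) {
  if (!is.null(fit)) {
    spec <- fit$spec; params <- fit$params
    if (is.null(scale)) scale <- fit$covScale
  }
  data <- prepareHMMData(steps, spec, scale)
  ld <- .emissionLogDens(data, spec, params)
  tp <- .transParts(data, params)
  as.integer(.hmmViterbiCpp(ld, tp$tr, as.integer(data$seg), tp$delta))
}

#' Stationary state probabilities along a covariate grid
#'
#' For each row of `newdata`, builds the transition matrix at those
#' covariates and solves delta Gamma = delta, sum(delta) = 1. Typical use
#' varies one covariate over a grid with the others fixed at reference
#' values, reproducing equilibrium state-probability curves.
#'
#' @param fit An [fitHMM()] object.
#' @param newdata Data.frame of covariates (raw scale; the fit's
#'   standardization is reapplied).
#' @return Data.frame with one `delta_k` column per state, attributes
#'   carried from the solver (reducible flags produce a warning).
#' @export
stationaryProbs <- function(fit, newdata) {
  d <- .prepCovariates(newdata, scale = fit$covScale)
  X <- stats::model.matrix(fit$spec$transitionFormula, d)
  tr <- transitionMatrices(fit$params$trans_beta, X, fit$spec$nbStates)
  out <- t(vapply(seq_len(nrow(X)), function(i)
    as.numeric(stationaryDistribution(tr[, , i])),
    numeric(fit$spec$nbStates)))
  colnames(out) <- paste0("delta_", seq_len(ncol(out)))
  cbind(newdata, as.data.frame(out))
}
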