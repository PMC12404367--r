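#' Continuous-time correlated random walk (integrated OU) fitting
#'
#' The movement model treats velocity as a 2-D Ornstein-Uhlenbeck process
#' (autocorrelation parameter `beta`, 1/hr; diffusion `sigma`) and position
#' as its integral. The exact Gaussian state-space form is evaluated by a
#' Kalman filter with per-fix observation covariance built from the Argos
#' error ellipse, and parameters are estimated by maximum likelihood.
#' Segments of one animal are independent likelihood blocks sharing
#' parameters.
#'
#' @name ctcrw
NULL

# exact discretization of the integrated OU process over dt hours
.iouMats <- function(beta, sigma, dt) {
  s2 <- sigma^2
  if (beta * dt < 1e-7) {              # integrated-random-walk limit
    T2 <- matrix(c(1, 0, dt, 1), 2, 2)
    Q2 <- s2 * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
  } else {
    phi <- exp(-beta * dt)
    T2 <- matrix(c(1, 0, (1 - phi) / beta, phi), 2, 2)
    qxx <- s2 / beta^2 * (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta))
    qxv <- s2 * (1 - phi)^2 / (2 * beta^2)
    qvv <- s2 * (1 - phi^2) / (2 * beta)
    Q2 <- matrix(c(qxx, qxv, qxv, qvv), 2, 2)
  }
  list(T4 = kronecker(diag(2), T2), Q4 = kronecker(diag(2), Q2))
}

# observation covariance (km^2) from an Argos error ellipse; orientation in
# degrees clockwise from north, SD along an axis = semi-axis / sqrt(2)
ellipseCov <- function(smaj_m, smin_m, eor_deg) {
  th <- eor_deg * pi / 180
  sa <- (smaj_m / 1000) / sqrt(2)
  sb <- (smin_m / 1000) / sqrt(2)
  R <- matrix(c(sin(th), cos(th), cos(th), -sin(th)), 2, 2)
  R %*% diag(c(sa^2, sb^2)) %*% t(R)
}

# Kalman filter (+ optional RTS smoother) for one segment.
# times (hr), obs 2-col matrix (NA rows = prediction-only), Rlist 2x2 per row.
.ctcrwKalman <- function(times, obs, Rlist, beta, sigma, smooth = FALSE,
                         diffuse_pos = 1e4) {
  n <- length(times)
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 3] <- 1
  first <- which(!is.na(obs[, 1]))[1]
  a <- c(obs[first, 1], 0, obs[first, 2], 0)
  svel <- if (beta > 1e-7) sigma^2 / (2 * beta) else sigma^2 * 1e4
  P <- diag(c(diffuse_pos, svel, diffuse_pos, svel))
  ll <- 0
  at <- matrix(0, n, 4); Pt <- array(0, c(4, 4, n))
  ap <- matrix(0, n, 4); Pp <- array(0, c(4, 4, n))
  Tt <- array(0, c(4, 4, n))
  for (t in seq_len(n)) {
    if (t > 1) {
      M <- .iouMats(beta, sigma, times[t] - times[t - 1])
      a <- as.numeric(M$T4 %*% a)
      P <- M$T4 %*% P %*% t(M$T4) + M$Q4
      Tt[, , t] <- M$T4
    }
    ap[t, ] <- a; Pp[, , t] <- P
    if (!is.na(obs[t, 1])) {
      v <- obs[t, ] - as.numeric(H %*% a)
      S <- H %*% P %*% t(H) + Rlist[[t]]
      Sc <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(Sc)) return(list(loglik = -Inf))
      Si_v <- backsolve(Sc, forwardsolve(t(Sc), v))
      ll <- ll - 0.5 * (2 * log(2 * pi) + 2 * sum(log(diag(Sc))) +
                          sum(v * Si_v))
      K <- P %*% t(H) %*% chol2inv(Sc)
      a <- a + as.numeric(K %*% v)
      P <- P - K %*% H %*% P
      P <- (P + t(P)) / 2
    }
    at[t, ] <- a; Pt[, , t] <- P
  }
  out <- list(loglik = ll)
  if (smooth) {
    as_ <- at; Ps <- Pt
    for (t in (n - 1):1) {
      if (n < 2) break
      J <- Pt[, , t] %*% t(Tt[, , t + 1]) %*% .pinv(Pp[, , t + 1])
      as_[t, ] <- at[t, ] + as.numeric(J %*% (as_[t + 1, ] - ap[t + 1, ]))
      Ps[, , t] <- Pt[, , t] +
        J %*% (Ps[, , t + 1] - Pp[, , t + 1]) %*% t(J)
      Ps[, , t] <- (Ps[, , t] + t(Ps[, , t])) / 2
    }
    out$smoothed <- as_
    out$smoothed_var <- Ps
  }
  out
}

.pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, nrow(M), ncol(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# segment data -> times/obs/R lists used by the filter
.ctcrwBlocks <- function(data, default_sd_km) {
  lapply(split(data, data$segment_id), function(d) {
    d <- d[order(d$timestamp), ]
    t0 <- d$timestamp[1]
    times <- as.numeric(difftime(d$timestamp, t0, units = "hours"))
    Rlist <- lapply(seq_len(nrow(d)), function(i) {
      if (!is.null(d$smaj) && is.finite(d$smaj[i]) && d$smaj[i] > 0)
        ellipseCov(d$smaj[i], d$smin[i], d$eor[i])
      else diag(default_sd_km^2, 2)
    })
    list(t0 = t0, times = times, obs = cbind(d$x, d$y), Rlist = Rlist,
         segment_id = d$segment_id[1], animal_id = d$animal_id[1])
  })
}

#' Fit the CTCRW model to segmented, projected locations
#'
#' @param data Data.frame with `animal_id`, `segment_id`, `timestamp`
#'   (POSIXct), planar `x`, `y` (km) and optional error-ellipse columns
#'   `smaj`, `smin` (m), `eor` (deg). Fixes without ellipse data get an
#'   isotropic `default_sd_km` observation SD.
#' @param n_starts Number of perturbed optimizer starts (default 3).
#' @param default_sd_km Observation SD for fixes without an ellipse.
#' @param fixed Optional `c(beta, sigma)` to evaluate without optimizing.
#' @param seed Seed for start perturbations.
#' @return A `ctcrwFit`: estimated `beta` (1/hr), `sigma`, log-likelihood,
#'   convergence info and the prepared segment blocks.
#' @export
fitCTCRW <- function(data, n_starts = 3, default_sd_km = 1.7, fixed = NULL,
                     seed = 1L) {
  need <- c("animal_id", "segment_id", "timestamp", "x", "y")
  stopifnot(all(need %in% colnames(data)))
  sizes <- table(data$segment_id)
  if (any(sizes < 4)) stop("every segment needs at least 4 fixes")
  blocks <- .ctcrwBlocks(data, default_sd_km)
  negll <- function(theta) {
    beta <- exp(theta[1]); sigma <- exp(theta[2])
    ll <- sum(vapply(blocks, function(b)
      .ctcrwKalman(b$times, b$obs, b$Rlist, beta, sigma)$loglik, numeric(1)))
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (!is.null(fixed)) {
    fit <- list(par = log(fixed), value = negll(log(fixed)), convergence = 0L)
  } else {
    set.seed(seed)
    scale0 <- stats::sd(c(diff(data$x), diff(data$y)), na.rm = TRUE)
    base <- c(log(1 / 6), log(max(scale0, 0.5)))
    fits <- lapply(seq_len(n_starts), function(s) {
      st <- base + if (s == 1) 0 else stats::rnorm(2, 0, 0.7)
      tryCatch(stats::optim(st, negll, method = "Nelder-Mead",
                            control = list(maxit = 500)),
               error = function(e) list(value = Inf, convergence = 99L))
    })
    vals <- vapply(fits, `[[`, numeric(1), "value")
    fit <- fits[[which.min(vals)]]
    if (!is.finite(fit$value) || fit$convergence > 1)
      warning("CTCRW optimization did not converge cleanly")
  }
  structure(list(beta = exp(fit$par[1]), sigma = exp(fit$par[2]),
                 loglik = -fit$value, convergence = fit$convergence,
                 blocks = blocks, default_sd_km = default_sd_km),
            class = "ctcrwFit")
}

#' @export
print.ctcrwFit <- function(x, ...) {
  cat("CTCRW fit:", length(x$blocks), "segment(s); beta =",
      signif(x$beta, 4), "per hr; sigma =", signif(x$sigma, 4),
      "; logLik =", round(x$loglik, 2), "\n")
  invisible(x)
}

#' Predict temporally-regular positions from a CTCRW fit
#'
#' Smoothed positions on a regular grid whose phase matches the tags' dive
#' windows: with the default 2-h interval and 03:00 GMT anchor, every 6-h
#' analysis window boundary (03/09/15/21 GMT) is a grid point. Predictions
#' are made only within each segment's observed span.
#'
#' @param fit A [fitCTCRW()] object.
#' @param interval_h Prediction interval in hours; must divide 24.
#' @param anchor_h GMT hour the grid is phased to (default 3).
#' @return Data.frame `animal_id`, `segment_id`, `time`, `x`, `y`, `vx`,
#'   `vy`, `var_x`, `var_y`.
#' @export
predictRegular <- function(fit, interval_h = 2, anchor_h = 3) {
  stopifnot(inherits(fit, "ctcrwFit"), 24 %% interval_h == 0)
  out <- lapply(fit$blocks, function(b) {
    span <- range(b$times)
    t0n <- as.numeric(b$t0)              # seconds since epoch, UTC
    sec0 <- t0n + span[1] * 3600
    sec1 <- t0n + span[2] * 3600
    step <- interval_h * 3600
    anchor <- anchor_h * 3600
    first <- ceiling((sec0 - anchor) / step) * step + anchor
    if (first > sec1) return(NULL)
    grid_sec <- seq(first, sec1, by = step)
    grid_hr <- (grid_sec - t0n) / 3600
    .ctcrwPredict(fit, b, grid_hr)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Smoothed state estimates at arbitrary times within a segment
#'
#' @param fit A [fitCTCRW()] object.
#' @param segment_id Segment to predict in.
#' @param times POSIXct times; must lie within the segment span.
#' @return As [predictRegular()].
#' @export
predictAt <- function(fit, segment_id, times) {
  ids <- vapply(fit$blocks, `[[`, character(1), "segment_id")
  b <- fit$blocks[[match(segment_id, ids)]]
  if (is.null(b)) stop("unknown segment ", segment_id)
  hr <- as.numeric(difftime(times, b$t0, units = "hours"))
  if (any(hr < min(b$times) - 1e-9 | hr > max(b$times) + 1e-9))
    stop("prediction outside segment span refused")
  .ctcrwPredict(fit, b, hr)
}

.ctcrwPredict <- function(fit, b, grid_hr) {
  all_t <- sort(unique(c(b$times, grid_hr)))
  m <- length(all_t)
  obs <- matrix(NA_real_, m, 2)
  Rlist <- vector("list", m)
  oi <- match(round(b$times, 9), round(all_t, 9))
  obs[oi, ] <- b$obs
  Rlist[oi] <- b$Rlist
  for (i in seq_len(m)) if (is.null(Rlist[[i]])) Rlist[[i]] <- diag(2)
  kf <- .ctcrwKalman(all_t, obs, Rlist, fit$beta, fit$sigma, smooth = TRUE)
  gi <- match(round(grid_hr, 9), round(all_t, 9))
  data.frame(animal_id = b$animal_id, segment_id = b$segment_id,
             time = b$t0 + grid_hr * 3600,
             x = kf$smoothed[gi, 1], y = kf$smoothed[gi, 3],
             vx = kf$smoothed[gi, 2], vy = kf$smoothed[gi, 4],
             var_x = kf$smoothed_var[1, 1, ][gi],
             var_y = kf$smoothed_var[3, 3, ][gi],
             stringsAsFactors = FALSE)
}
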