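#' Covariate-dependent transition probability matrices
#'
#' Transition probabilities follow a multinomial logit: for row (origin
#' state) i, the diagonal (staying put) is the reference category and each
#' off-diagonal entry j gets a linear predictor eta_ij = X beta_ij, so
#' Gamma_ij = exp(eta_ij) / (1 + sum_k exp(eta_ik)). Off-diagonal entries
#' are ordered (1,2), (1,3), ..., i.e. row-wise skipping the diagonal.
#'
#' @param beta Numeric matrix, `ncol(X)` rows by `K*(K-1)` columns of
#'   multinomial-logit coefficients.
#' @param X Design matrix (steps by covariate columns).
#' @param K Number of states.
#' @return Array `K x K x nrow(X)` of row-stochastic matrices.
#' @export
transitionMatrices <- function(beta, X, K = 3) {
  X <- as.matrix(X)
  stopifnot(nrow(beta) == ncol(X), ncol(beta) == K * (K - 1))
  eta <- X %*% beta                      # T x K(K-1)
  Tn <- nrow(X)
  out <- array(0, dim = c(K, K, Tn))
  col <- 0L
  expeta <- exp(eta)
  for (i in seq_len(K)) {
    js <- setdiff(seq_len(K), i)
    denom <- 1 + rowSums(expeta[, col + seq_along(js), drop = FALSE])
    out[i, i, ] <- 1 / denom
    for (m in seq_along(js)) {
      out[i, js[m], ] <- expeta[, col + m] / denom
    }
    col <- col + length(js)
  }
  out
}

# Convert a fixed row-stochastic matrix to intercept-only logit coefficients
# (inverse of transitionMatrices at X = 1).
.logitFromMatrix <- function(Gamma) {
  K <- nrow(Gamma)
  stopifnot(ncol(Gamma) == K, all(Gamma >= 0),
            all(abs(rowSums(Gamma) - 1) < 1e-8))
  if (any(diag(Gamma) <= 0)) stop("diagonal entries must be positive")
  beta <- numeric(0)
  for (i in seq_len(K)) {
    js <- setdiff(seq_len(K), i)
    beta <- c(beta, log(Gamma[i, js] / Gamma[i, i]))
  }
  matrix(beta, nrow = 1)
}

#' Stationary distribution of a transition matrix
#'
#' Solves delta Gamma = delta, sum(delta) = 1 by the standard linear system;
#' if the matrix is reducible (singular system), falls back to the left
#' null-space via eigen-decomposition and flags the result.
#'
#' @param Gamma A K x K row-stochastic matrix.
#' @return Numeric vector delta of length K (attribute `reducible` set TRUE
#'   when the fallback solver was used).
#' @export
stationaryDistribution <- function(Gamma) {
  K <- nrow(Gamma)
  A <- t(diag(K) - Gamma + matrix(1, K, K))
  delta <- tryCatch(solve(A, rep(1, K)), error = function(e) NULL)
  if (is.null(delta) || any(!is.finite(delta))) {
    ev <- eigen(t(Gamma))
    i <- which.min(abs(ev$values - 1))
    delta <- Re(ev$vectors[, i])
    delta <- delta / sum(delta)
    attr(delta, "reducible") <- TRUE
    warning("transition matrix appears reducible; stationary distribution ",
            "taken from the unit-eigenvalue left eigenvector")
  }
  delta
}
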