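#' Convert gamma mean/SD to shape/rate
#'
#' The gamma emission distributions are parameterized by mean and standard
#' deviation on the user-facing side (the scale on which state estimates are
#' reported) and by shape/rate internally for density evaluation.
#'
#' @param mean,sd Positive numerics (recycled).
#' @return A list with components `shape` and `rate`.
#' @seealso [gammaMeanSD()] for the inverse.
#' @export
#' @examples
#' p <- gammaShapeRate(100, 25)
#' gammaMeanSD(p$shape, p$rate)
gammaShapeRate <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Convert gamma shape/rate to mean/SD
#' @param shape,rate Positive numerics (recycled).
#' @return A list with components `mean` and `sd`.
#' @export
gammaMeanSD <- function(shape, rate) {
  stopifnot(all(shape > 0), all(rate > 0))
  list(mean = shape / rate, sd = sqrt(shape) / rate)
}

#' Convert Weibull mean/SD to shape/scale
#'
#' Inverts the moment relations mean = scale * Gamma(1 + 1/shape) and
#' CV^2 = Gamma(1 + 2/shape) / Gamma(1 + 1/shape)^2 - 1 by a monotone
#' root search in the coefficient of variation.
#'
#' @param mean,sd Positive numerics (recycled to common length).
#' @return A list with components `shape` and `scale`.
#' @export
weibullShapeScale <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  n <- max(length(mean), length(sd))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  cv2fun <- function(k) exp(lgamma(1 + 2 / k) - 2 * lgamma(1 + 1 / k)) - 1
  shape <- vapply(sd / mean, function(cv) {
    stats::uniroot(function(k) cv2fun(k) - cv^2,
                   lower = 0.02, upper = 200, tol = 1e-12)$root
  }, numeric(1))
  list(shape = shape, scale = mean / gamma(1 + 1 / shape))
}

#' Convert Weibull shape/scale to mean/SD
#' @param shape,scale Positive numerics (recycled).
#' @return A list with components `mean` and `sd`.
#' @export
weibullMeanSD <- function(shape, scale) {
  stopifnot(all(shape > 0), all(scale > 0))
  m <- scale * gamma(1 + 1 / shape)
  v <- scale^2 * (gamma(1 + 2 / shape) - gamma(1 + 1 / shape)^2)
  list(mean = m, sd = sqrt(v))
}

# log(sum(exp(x))) without overflow
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
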