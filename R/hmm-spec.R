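#' Specification of the 3-state hidden Markov model
#'
#' Defines the emission families and covariate formulas of the behavioural
#' HMM. Streams Ms, Tr, Sf and Dp use gamma emissions (parameterized by
#' mean and SD), Md and Rd use Weibull (shape and scale); Dp carries an
#' extra state-specific zero-mass probability for windows with no deep
#' time. Each stream has one formula per state applied to BOTH natural
#' parameters through a log link (which keeps them positive); the default
#' formulas encode the published covariate structure: bathymetry on the
#' dive streams for the diving states (2 and 3) only, winter day on surface
#' time in all states, and a tag-programming intercept on Md, Rd and Dp.
#' Transition probabilities are multinomial-logit in the transition formula
#' (default: winter day, bathymetry, slope, shore distance and the 24-h
#' cosinor pair).
#'
#' Covariates named in formulas must exist in the step table; `bath`,
#' `wday`, `slope` and `shore` are z-scored internally, `prog` is a factor
#' with `"2010+"` as reference, and `cos_hour`/`sin_hour` are derived from
#' the local hour.
#'
#' @param nbStates Number of states (3).
#' @param emission Named list per stream: `dist` ("gamma"/"weibull"),
#'   `zeromass` flag, `formulas` list of per-state formulas.
#' @param transitionFormula Formula for the transition linear predictors.
#' @return An object of class `hmmSpec`.
#' @export
hmmSpec <- function(nbStates = 3,
                    emission = defaultEmissionSpec(),
                    transitionFormula = ~ wday + bath + slope + shore +
                      cos_hour + sin_hour) {
  stopifnot(nbStates == 3)
  for (s in names(emission)) {
    e <- emission[[s]]
    stopifnot(e$dist %in% c("gamma", "weibull"),
              length(e$formulas) == nbStates)
    if (isTRUE(e$zeromass) && e$dist != "gamma")
      stop("zero-mass only supported on gamma streams")
  }
  structure(list(nbStates = nbStates, emission = emission,
                 transitionFormula = transitionFormula),
            class = "hmmSpec")
}

#' @rdname hmmSpec
#' @export
defaultEmissionSpec <- function() {
  list(
    Ms = list(dist = "gamma", zeromass = FALSE,
              formulas = list(~1, ~1, ~1)),
    Tr = list(dist = "gamma", zeromass = FALSE,
              formulas = list(~1, ~1, ~1)),
    Sf = list(dist = "gamma", zeromass = FALSE,
              formulas = list(~wday, ~ wday + bath, ~ wday + bath)),
    Md = list(dist = "weibull", zeromass = FALSE,
              formulas = list(~prog, ~ prog + bath, ~ prog + bath)),
    Rd = list(dist = "weibull", zeromass = FALSE,
              formulas = list(~prog, ~ prog + bath, ~ prog + bath)),
    Dp = list(dist = "gamma", zeromass = TRUE,
              formulas = list(~prog, ~ prog + bath, ~ prog + bath))
  )
}

#' @rdname hmmSpec
#' @export
interceptOnlySpec <- function() {
  one <- list(~1, ~1, ~1)
  hmmSpec(emission = list(
    Ms = list(dist = "gamma", zeromass = FALSE, formulas = one),
    Tr = list(dist = "gamma", zeromass = FALSE, formulas = one),
    Sf = list(dist = "gamma", zeromass = FALSE, formulas = one),
    Md = list(dist = "weibull", zeromass = FALSE, formulas = one),
    Rd = list(dist = "weibull", zeromass = FALSE, formulas = one),
    Dp = list(dist = "gamma", zeromass = TRUE, formulas = one)
  ), transitionFormula = ~1)
}

#' @export
print.hmmSpec <- function(x, ...) {
  cat("hmmSpec:", x$nbStates, "states;",
      length(x$emission), "streams (",
      paste(names(x$emission), collapse = ", "), ")\n")
  cat("  transition: ", deparse(x$transitionFormula), "\n")
  invisible(x)
}

# z-score the standard covariates; derive cosinor columns; normalize prog.
# `scale` from a previous call reapplies the same centring (for newdata).
.prepCovariates <- function(steps, scale = NULL) {
  d <- steps
  if (!is.null(d$hour)) {
    d$cos_hour <- cos(2 * pi * d$hour / 24)
    d$sin_hour <- sin(2 * pi * d$hour / 24)
  }
  if (!is.null(d$prog))
    d$prog <- factor(as.character(d$prog), levels = c("2010+", "2009"))
  std <- intersect(c("bath", "wday", "slope", "shore"), colnames(d))
  if (is.null(scale)) {
    scale <- lapply(std, function(v)
      c(center = mean(d[[v]], na.rm = TRUE),
        scale = max(stats::sd(d[[v]], na.rm = TRUE), 1e-9)))
    names(scale) <- std
  }
  for (v in intersect(std, names(scale)))
    d[[v]] <- (d[[v]] - scale[[v]]["center"]) / scale[[v]]["scale"]
  attr(d, "covScale") <- scale
  d
}

# Build all design matrices and bookkeeping for likelihood evaluation.
prepareHMMData <- function(steps, spec, scale = NULL) {
  stopifnot(inherits(spec, "hmmSpec"))
  if (is.null(steps$segment_id)) steps$segment_id <- "seg1"
  d <- .prepCovariates(steps, scale)
  K <- spec$nbStates
  Xe <- list()
  for (s in names(spec$emission)) {
    Xe[[s]] <- lapply(seq_len(K), function(k)
      stats::model.matrix(spec$emission[[s]]$formulas[[k]], d))
    if (any(vapply(Xe[[s]], nrow, integer(1)) != nrow(d)))
      stop("missing covariate values for stream ", s,
           " (covariates may not be missing)")
  }
  Xt <- stats::model.matrix(spec$transitionFormula, d)
  if (nrow(Xt) != nrow(d)) stop("missing transition covariate values")
  seg <- match(steps$segment_id, unique(steps$segment_id))
  obs <- as.matrix(steps[names(spec$emission)])
  if (any(obs < 0, na.rm = TRUE)) stop("negative stream value")
  list(steps = steps, obs = obs, Xe = Xe, Xt = Xt, seg = seg,
       covScale = attr(d, "covScale"), K = K)
}
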