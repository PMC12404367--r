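#' Rasterize decoded states to a grid
#'
#' Counts decoded 6-h steps per grid cell, total and per state. Steps
#' outside the extent are accumulated in an overflow count and reported via
#' a message.
#'
#' @param x,y Planar step coordinates (km).
#' @param states Decoded states (integers in 1..K).
#' @param cell_km Cell size (default 50, the scale of the published state
#'   maps; the analysis grid is configurable).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; default snug around
#'   the data.
#' @param K Number of states.
#' @return An object of class `cellStateStats`: list with `N` (cells
#'   matrix), `NS` (cells x states array), cell geometry, global totals and
#'   the overflow count.
#' @export
rasterizeStates <- function(x, y, states, cell_km = 50, extent = NULL, K = 3) {
  stopifnot(length(x) == length(y), length(x) == length(states),
            all(states %in% seq_len(K)))
  if (is.null(extent))
    extent <- c(floor(min(x)), ceiling(max(x) + 1e-9),
                floor(min(y)), ceiling(max(y) + 1e-9))
  nx <- max(1, ceiling((extent[2] - extent[1]) / cell_km))
  ny <- max(1, ceiling((extent[4] - extent[3]) / cell_km))
  j <- ceiling((x - extent[1]) / cell_km)
  i <- ceiling((y - extent[3]) / cell_km)
  j[j == 0] <- 1L; i[i == 0] <- 1L
  inside <- i >= 1 & i <= ny & j >= 1 & j <= nx
  overflow <- sum(!inside)
  if (overflow > 0)
    message(overflow, " step(s) outside the extent counted in overflow")
  N <- matrix(0L, ny, nx)
  NS <- array(0L, dim = c(ny, nx, K))
  for (t in which(inside)) {
    N[i[t], j[t]] <- N[i[t], j[t]] + 1L
    NS[i[t], j[t], states[t]] <- NS[i[t], j[t], states[t]] + 1L
  }
  structure(list(N = N, NS = NS, cell_km = cell_km,
                 origin = extent[c(1, 3)], K = K,
                 N_total = sum(N), NS_total = apply(NS, 3, sum),
                 overflow = overflow),
            class = "cellStateStats")
}

#' @export
print.cellStateStats <- function(x, ...) {
  cat("cellStateStats:", nrow(x$N), "x", ncol(x$N), "cells at", x$cell_km,
      "km;", x$N_total, "steps; per state:",
      paste(x$NS_total, collapse = "/"), "\n")
  invisible(x)
}

#' Disproportionate state per cell
#'
#' For each cell i the statistic picks the state whose within-cell
#' frequency is largest relative to its global frequency:
#' `S'_i = argmax_S (N_i(S) / N_i) / (N(S) / N)`. This highlights where a
#' behaviour concentrates without the map being swamped by globally-common
#' states. Cells with fewer than `min_plot` steps are masked (NA); cells
#' with fewer than `min_confident` are flagged low-certainty. Ties break
#' toward the lower state index.
#'
#' @param stats A [rasterizeStates()] object.
#' @param min_plot Mask threshold (default 4 steps).
#' @param min_confident Low-certainty threshold (default 16 steps).
#' @return List of matrices: `sprime` (state index or NA), `low_certainty`
#'   (logical), `ratio` (the winning ratio).
#' @export
disproportionateState <- function(stats, min_plot = 4, min_confident = 16) {
  stopifnot(inherits(stats, "cellStateStats"))
  gf <- stats$NS_total / stats$N_total
  if (any(stats$NS_total == 0 & apply(stats$NS, 3, sum) > 0))
    stop("inconsistent global state counts")
  present <- gf > 0
  ny <- nrow(stats$N); nx <- ncol(stats$N)
  sprime <- matrix(NA_integer_, ny, nx)
  ratio <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    n <- stats$N[i, j]
    if (n < min_plot) next
    rr <- rep(-Inf, stats$K)
    rr[present] <- (stats$NS[i, j, present] / n) / gf[present]
    sprime[i, j] <- which.max(rr)       # which.max takes the first = lowest
    ratio[i, j] <- max(rr)
  }
  list(sprime = sprime,
       low_certainty = !is.na(sprime) & stats$N < min_confident,
       ratio = ratio)
}

#' Dive-to-bottom proportions and maps
#'
#' Per step, the maximum dive depth (midpoint of the deepest non-empty DMD
#' bin) as a proportion of the available bathymetry, capped at 1; also the
#' overall and per-state fraction of steps reaching at least
#' `benthic_threshold` (default 0.75) of the bottom.
#'
#' @param max_depth Per-step maximum dive depth (m); steps with missing DMD
#'   records are skipped with a message.
#' @param bath Per-step bathymetry (m, > 0).
#' @param states Optional decoded states for per-state summaries.
#' @param benthic_threshold Proportion defining a near-benthic dive.
#' @return List with `proportion` (per step, NA where skipped),
#'   `frac_benthic` and optionally `frac_benthic_by_state`.
#' @export
diveToBottomMap <- function(max_depth, bath, states = NULL,
                            benthic_threshold = 0.75) {
  stopifnot(length(max_depth) == length(bath), all(bath > 0, na.rm = TRUE))
  skip <- is.na(max_depth)
  if (any(skip)) message(sum(skip), " step(s) without DMD record skipped")
  prop <- ifelse(skip, NA_real_, pmin(max_depth / bath, 1))
  out <- list(proportion = prop,
              frac_benthic = mean(prop >= benthic_threshold, na.rm = TRUE))
  if (!is.null(states)) {
    out$frac_benthic_by_state <- vapply(sort(unique(states)), function(k)
      mean(prop[states == k] >= benthic_threshold, na.rm = TRUE), numeric(1))
    names(out$frac_benthic_by_state) <- paste0("state", sort(unique(states)))
  }
  out
}

#' Maximum dive depth from a DMD histogram
#'
#' @param dmd Counts per depth bin.
#' @param prog Tag-programming dialect.
#' @return Midpoint (m) of the deepest non-empty bin, or NA if all empty.
#' @export
maxDepthFromDMD <- function(dmd, prog) {
  mids <- diveBinMidpoints(prog)
  stopifnot(length(dmd) == length(mids))
  nz <- which(dmd > 0)
  if (!length(nz)) return(NA_real_)
  mids[max(nz)]
}

#' Overall behavioural time budget
#'
#' Fraction of decoded steps per state; sums to 1.
#'
#' @param states Decoded state path.
#' @param K Number of states.
#' @return Named numeric vector of length K.
#' @export
stateTimeBudget <- function(states, K = 3) {
  stopifnot(length(states) > 0, all(states %in% seq_len(K)))
  tb <- tabulate(states, nbins = K) / length(states)
  names(tb) <- paste0("state", seq_len(K))
  tb
}
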