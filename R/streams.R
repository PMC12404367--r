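#' Tortuosity of a three-step path
#'
#' Tortuosity at step t is the ratio of the three-step path length
#' L(t,t+1) + L(t+1,t+2) + L(t+2,t+3) to the straight-line distance
#' D(t,t+3), minus 1, so a straight path scores 0 (supporting a gamma
#' emission on values > 0).
#'
#' @param x,y Planar coordinates (km) of four consecutive step positions,
#'   or matrices/vectors of length 4.
#' @return Non-negative tortuosity, or `NA` when the straight-line distance
#'   is zero (closed loop).
#' @export
#' @examples
#' computeTortuosity(c(0, 1, 1, 0), c(0, 0, 1, 1))  # square path: 3/1 - 1 = 2
computeTortuosity <- function(x, y) {
  stopifnot(length(x) == 4, length(y) == 4, all(is.finite(x)), all(is.finite(y)))
  L <- sum(sqrt(diff(x)^2 + diff(y)^2))
  D <- sqrt((x[4] - x[1])^2 + (y[4] - y[1])^2)
  if (D == 0) {
    message("tortuosity undefined for closed loop (D = 0); returning NA")
    return(NA_real_)
  }
  L / D - 1
}

#' Mean speed over a 6-hour window
#'
#' Sum of consecutive segment lengths between the regular within-window
#' positions, divided by the elapsed time, in m/hr.
#'
#' @param x,y Planar positions (km) at the regular within-window times.
#' @param times POSIXct times of those positions.
#' @return Mean speed in m/hr, or `NA` with fewer than 2 positions.
#' @export
computeMeanSpeed <- function(x, y, times) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  stopifnot(length(y) == n, length(times) == n)
  path_km <- sum(sqrt(diff(x)^2 + diff(y)^2))
  hours <- as.numeric(difftime(times[n], times[1], units = "hours"))
  if (hours <= 0) return(NA_real_)
  path_km * 1000 / hours
}

#' Dive data streams from one binned dive record
#'
#' Computes the four dive streams from a TAD histogram: surface time Sf
#' (percent of the window shallower than 6 m), time at depth Dp (percent
#' deeper than 400 m), mean depth Md (TAD-weighted mean of sub-surface bin
#' midpoints, the surface bin excluded) and relative dive depth
#' Rd = Md / bath capped at 1. Bins straddling the 6-m or 400-m boundary
#' have their mass apportioned linearly by depth-range overlap.
#'
#' @param tad Numeric vector of TAD percentages (sums to 100).
#' @param prog Tag-programming dialect (see [diveBinEdges()]).
#' @param bath Bathymetry (m) at the step, for Rd.
#' @param surface_m,deep_m Stream boundaries (default 6 and 400 m).
#' @return List with `Sf`, `Md`, `Rd`, `Dp`.
#' @export
computeDiveStreams <- function(tad, prog, bath, surface_m = 6, deep_m = 400) {
  edges <- diveBinEdges(prog)
  nb <- length(edges) - 1
  if (length(tad) != nb)
    stop("TAD vector has ", length(tad), " bins; dialect '", prog,
         "' expects ", nb)
  stopifnot(all(tad >= -1e-9), abs(sum(tad) - 100) < 0.5)
  fr_surface <- .binOverlapFrac(edges, 0, surface_m)
  fr_deep <- .binOverlapFrac(edges, deep_m, Inf)
  Sf <- sum(tad * fr_surface)
  Dp <- sum(tad * fr_deep)

  mids <- diveBinMidpoints(prog)
  l <- edges[-length(edges)]; u <- edges[-1]
  sub_mass <- tad * (1 - fr_surface)
  # midpoint of the sub-surface portion of a straddling bin
  sub_mid <- ifelse(l < surface_m & u > surface_m, (surface_m + pmin(u, 1e9)) / 2,
                    mids)
  Md <- if (sum(sub_mass) > 0) sum(sub_mass * sub_mid) / sum(sub_mass)
        else NA_real_
  Rd <- if (!is.na(Md) && !is.na(bath) && bath > 0) min(Md / bath, 1)
        else NA_real_
  list(Sf = Sf, Md = Md, Rd = Rd, Dp = Dp)
}

#' Extract per-step covariates
#'
#' Covariates at a predicted position and time: `bath` the maximum
#' bathymetry within a 20-km buffer (animals can travel far within a 6-h
#' window, and the stream boundaries relate to the deepest water
#' available), `slope` the mean seafloor slope within the buffer, `shore`
#' the distance to the nearest 0-m cell (km), `hour` the local clock hour
#' (UTC-4, decimal), and `wday` days since September 1 of the season's
#' start year.
#'
#' @param x,y Planar positions (km) inside the raster extent.
#' @param time POSIXct (GMT) times.
#' @param env An `envRaster`.
#' @param buffer_km Buffer radius (default 20).
#' @param tz_offset_h Local-time offset from UTC (default -4).
#' @return data.frame with columns `bath`, `slope`, `shore`, `hour`, `wday`.
#' @export
extractCovariates <- function(x, y, time, env, buffer_km = 20,
                              tz_offset_h = -4) {
  ext <- envExtent(env)
  if (any(x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]))
    stop("position outside raster extent")
  n <- length(x)
  bath <- numeric(n); slope <- numeric(n)
  ny <- nrow(env$bathymetry); nx <- ncol(env$bathymetry)
  r <- ceiling(buffer_km / env$res)
  for (i in seq_len(n)) {
    j0 <- ceiling((x[i] - env$origin[1]) / env$res)
    i0 <- ceiling((y[i] - env$origin[2]) / env$res)
    js <- max(1, j0 - r):min(nx, j0 + r)
    is <- max(1, i0 - r):min(ny, i0 + r)
    cx <- env$origin[1] + (js - 0.5) * env$res
    cy <- env$origin[2] + (is - 0.5) * env$res
    d2 <- outer((cy - y[i])^2, (cx - x[i])^2, `+`)
    inb <- d2 <= buffer_km^2
    if (!any(inb)) inb[which.min(d2)] <- TRUE
    bb <- env$bathymetry[is, js, drop = FALSE]
    ss <- env$slope[is, js, drop = FALSE]
    bath[i] <- max(bb[inb])
    slope[i] <- mean(ss[inb])
  }
  shore <- envLookup(env, x, y, "shore")
  hour <- (as.numeric(format(time, "%H", tz = "UTC")) +
             as.numeric(format(time, "%M", tz = "UTC")) / 60 +
             tz_offset_h) %% 24
  data.frame(bath = bath, slope = slope, shore = shore,
             hour = hour, wday = .winterDay(time))
}

#' Build the HMM step table from regularized positions and dive records
#'
#' Assembles one StepRecord per 6-hour analysis window (anchored at 03:00
#' GMT, matching the tags' dive windows): mean speed from the 2-h positions
#' within the window, tortuosity over the next three step positions (the
#' last three steps of a segment are missing by construction), the four
#' dive streams from the matching binned dive record, and the five
#' covariates at the window-start position.
#'
#' @param pred Data.frame of regular predicted positions with columns
#'   `animal_id`, `segment_id`, `time` (POSIXct GMT), `x`, `y` (km).
#' @param divebins Data.frame of dive records (as from [degradeToArgos()] or
#'   [readDiveBins()]), matched on `animal_id` + `window_start`.
#' @param env An `envRaster` for covariates.
#' @param prog Tag-programming dialect of the dive records.
#' @param interval_h Spacing of `pred` positions (default 2).
#' @return StepRecord data.frame (one row per complete 6-h window).
#' @export
buildSteps <- function(pred, divebins, env, prog, interval_h = 2) {
  stopifnot(all(c("animal_id", "segment_id", "time", "x", "y") %in%
                  colnames(pred)))
  per_win <- 6 / interval_h
  out <- list()
  tadcols <- grep("^tad_", colnames(divebins))
  key <- paste(divebins$animal_id, format(divebins$window_start, tz = "UTC"))
  for (seg in split(pred, list(pred$animal_id, pred$segment_id), drop = TRUE)) {
    seg <- seg[order(seg$time), ]
    hrs <- as.numeric(format(seg$time, "%H", tz = "UTC"))
    w0 <- which(hrs %% 6 == 3)           # window starts 03/09/15/21 GMT
    w0 <- w0[w0 + per_win <= nrow(seg)]
    if (!length(w0)) next
    n_w <- length(w0)
    Ms <- vapply(w0, function(i) {
      idx <- i:(i + per_win)
      computeMeanSpeed(seg$x[idx], seg$y[idx], seg$time[idx])
    }, numeric(1))
    Tr <- rep(NA_real_, n_w)
    for (m in seq_len(n_w)) {
      if (m + 3 <= n_w && w0[m + 3] - w0[m] == 3 * per_win) {
        ii <- w0[c(m, m + 1, m + 2, m + 3)]
        Tr[m] <- suppressMessages(computeTortuosity(seg$x[ii], seg$y[ii]))
      }
    }
    cov <- extractCovariates(seg$x[w0], seg$y[w0], seg$time[w0], env)
    Sf <- Md <- Rd <- Dp <- rep(NA_real_, n_w)
    mk <- match(paste(seg$animal_id[w0], format(seg$time[w0], tz = "UTC")), key)
    for (m in which(!is.na(mk))) {
      ds <- computeDiveStreams(as.numeric(divebins[mk[m], tadcols]),
                               prog = prog, bath = cov$bath[m])
      Sf[m] <- ds$Sf; Md[m] <- ds$Md; Rd[m] <- ds$Rd; Dp[m] <- ds$Dp
    }
    out[[length(out) + 1]] <- data.frame(
      animal_id = seg$animal_id[1], segment_id = seg$segment_id[1],
      step_time = seg$time[w0], x = seg$x[w0], y = seg$y[w0],
      Ms = Ms, Tr = Tr, Sf = Sf, Md = Md, Rd = Rd, Dp = Dp,
      cov, prog = prog, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no complete 6-h windows found")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
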