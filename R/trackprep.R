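#' Clean raw location records
#'
#' Standard telemetry hygiene: within each animal, duplicate timestamps are
#' collapsed keeping the fix with the smaller error ellipse; spike outliers
#' are removed by a course speed filter (a fix goes when the speeds implied
#' to BOTH temporal neighbours exceed `max_speed`, which removes error
#' spikes while keeping genuine fast transit); and, when an environment is
#' supplied, fixes falling on land (bathymetry 0) are dropped. The spike
#' filter is applied repeatedly until no fix moves, making cleaning
#' idempotent.
#'
#' @param records Location data.frame with columns `animal_id`, `timestamp`
#'   (POSIXct), `lon`, `lat` and optionally `smaj`, `smin`, `eor` (m / deg).
#' @param max_speed Speed threshold in m/s (default 10).
#' @param env Optional `envRaster` for the on-land test.
#' @param center Projection centre (lon, lat); default from `env` or data.
#' @return The cleaned data.frame, sorted by animal and time.
#' @export
cleanLocations <- function(records, max_speed = 10, env = NULL,
                           center = NULL) {
  stopifnot(max_speed > 0)
  if (nrow(records) == 0) {
    warning("empty location table")
    return(records)
  }
  if (is.null(center))
    center <- if (!is.null(env)) env$center else
      c(mean(records$lon), mean(records$lat))
  ord <- order(records$animal_id, records$timestamp,
               if (!is.null(records$smaj)) records$smaj else
                 seq_len(nrow(records)))
  records <- records[ord, ]
  dup <- duplicated(records[, c("animal_id", "timestamp")])
  records <- records[!dup, ]

  xy <- projectAEQD(records$lon, records$lat, center)
  records$.x <- xy$x; records$.y <- xy$y
  if (!is.null(env)) {
    onland <- envLookup(env, records$.x, records$.y) == 0
    records <- records[!onland, ]
  }

  pieces <- lapply(split(records, records$animal_id), function(d) {
    repeat {
      n <- nrow(d)
      if (n < 3) break
      dt <- as.numeric(diff(d$timestamp), units = "secs")
      dd <- sqrt(diff(d$.x)^2 + diff(d$.y)^2) * 1000
      sp <- ifelse(dt > 0, dd / dt, Inf)
      bad <- c(FALSE, sp > max_speed) & c(sp > max_speed, FALSE)
      if (!any(bad)) break
      d <- d[!bad, ]
    }
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$.x <- NULL; out$.y <- NULL
  out
}

#' Delineate the winter residency window
#'
#' Automates the visual rule used for duty-cycled whale tracks: migration
#' shows as a trend in the (z-scored) southward coordinate and in surface
#' time, residency as their joint stabilization. Both series are smoothed
#' with a rolling mean and a single least-squares change-point is fit to
#' the stacked standardized series; the change date is the start of winter.
#' A manual override always wins. If no convincing change-point exists
#' (relative RSS reduction below `min_gain`) the whole range is returned
#' with a low-confidence flag.
#'
#' @param dates Vector of dates/POSIXct (one per observation, increasing).
#' @param ycoord Southward (projected y) coordinate series.
#' @param surface Surface-time series (same length).
#' @param window Rolling-mean window in observations (default 5).
#' @param min_gain Minimum relative RSS reduction to accept the
#'   change-point (default 0.2).
#' @param override Optional length-2 vector of first/last winter dates;
#'   returned unchanged when supplied.
#' @return List with `first`, `last` (dates) and `confident` (logical).
#' @export
delineateWinter <- function(dates, ycoord, surface, window = 5,
                            min_gain = 0.2, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2)
    return(list(first = override[1], last = override[2], confident = TRUE))
  }
  n <- length(dates)
  stopifnot(length(ycoord) == n, length(surface) == n)
  if (as.numeric(difftime(max(dates), min(dates), units = "days")) < 20)
    stop("need at least 20 days of data to delineate winter")
  zraw <- function(v)
    (v - mean(v, na.rm = TRUE)) / max(stats::sd(v, na.rm = TRUE), 1e-12)
  smooth <- function(v) {
    sm <- stats::filter(v, rep(1 / window, window), sides = 2)
    ifelse(is.na(sm), v, as.numeric(sm))
  }
  Yraw <- cbind(zraw(ycoord), zraw(surface))
  Y <- apply(Yraw, 2, smooth)
  rss <- function(v) sum((v - mean(v))^2)
  cand <- seq(3, n - 2)
  split_rss <- vapply(cand, function(k) {
    sum(apply(Y[1:k, , drop = FALSE], 2, rss)) +
      sum(apply(Y[(k + 1):n, , drop = FALSE], 2, rss))
  }, numeric(1))
  k <- cand[which.min(split_rss)]
  # confidence judged on the unsmoothed series: rolling-mean smoothing
  # manufactures apparent change-points in pure noise
  raw_split <- sum(apply(Yraw[1:k, , drop = FALSE], 2, rss)) +
    sum(apply(Yraw[(k + 1):n, , drop = FALSE], 2, rss))
  gain <- 1 - raw_split / max(sum(apply(Yraw, 2, rss)), 1e-12)
  if (gain < min_gain) {
    return(list(first = dates[1], last = dates[n], confident = FALSE))
  }
  # constant series from the start: change-point gain is ~0 and handled
  # above; otherwise winter starts right after the detected change
  list(first = dates[min(k + 1, n)], last = dates[n], confident = TRUE)
}

#' Split a track at long data gaps
#'
#' Duty-cycled tags leave multi-day holes; interpolating across them would
#' fabricate straight-line movement, so tracks are cut wherever the gap
#' between consecutive records (locations or dive records combined)
#' strictly exceeds the threshold. Segments left with fewer than
#' `min_records` records are dropped with a message.
#'
#' @param records Data.frame with `animal_id` and `timestamp` columns,
#'   sorted by time within animal.
#' @param gap_days Gap threshold in days (default 7).
#' @param min_records Minimum records for a segment to survive (default 4).
#' @return The input with a `segment_id` column added (`"<animal>_<k>"`),
#'   short segments removed.
#' @export
segmentTrack <- function(records, gap_days = 7, min_records = 4) {
  stopifnot(gap_days > 0)
  pieces <- lapply(split(records, records$animal_id), function(d) {
    d <- d[order(d$timestamp), ]
    gaps <- as.numeric(diff(d$timestamp), units = "days")
    seg <- cumsum(c(1, gaps > gap_days))
    d$segment_id <- paste0(d$animal_id[1], "_", seg)
    sizes <- table(d$segment_id)
    drop <- names(sizes)[sizes < min_records]
    if (length(drop))
      message("dropping ", length(drop), " short segment(s) of animal ",
              d$animal_id[1])
    d[!d$segment_id %in% drop, ]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
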