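# parse ISO-8601 timestamps (T or space separator), NA where malformed
.parseUTC <- function(x) {
  ts <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  na <- is.na(ts)
  if (any(na))
    ts[na] <- as.POSIXct(strptime(x[na], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  ts
}

#' Read and write location tables
#'
#' Locations travel as CSV with Argos-like columns: `animal_id`,
#' `timestamp` (ISO-8601, UTC), `lon`, `lat` and error-ellipse columns
#' `smaj`, `smin` (m), `eor` (deg). Unknown columns are preserved.
#'
#' @param path CSV file path.
#' @return Data.frame with `timestamp` parsed to POSIXct (UTC).
#' @export
readLocations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "lon", "lat")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) stop("locations file missing column(s): ",
                         paste(miss, collapse = ", "))
  ts <- .parseUTC(d$timestamp)
  if (any(is.na(ts)))
    stop("malformed timestamp at row(s) ",
         paste(utils::head(which(is.na(ts)), 5), collapse = ", "))
  if (any(abs(d$lat) > 90))
    stop("latitude out of range at row(s) ",
         paste(utils::head(which(abs(d$lat) > 90), 5), collapse = ", "))
  d$timestamp <- ts
  d
}

#' @rdname readLocations
#' @param locations Data.frame as produced by the package.
#' @export
writeLocations <- function(locations, path) {
  d <- locations
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read and write binned dive records
#'
#' Dive records are CSV with `animal_id`, `window_start` (ISO-8601 GMT),
#' `prog` and per-bin `tad_*` (percent) / `dmd_*` (count) columns. The bin
#' count must match the tag-programming dialect, guarding against parsing a
#' file with the wrong dialect.
#'
#' @param path CSV file path.
#' @param prog Expected dialect (`"2009"` or `"2010+"`).
#' @export
readDiveBins <- function(path, prog) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  nb <- length(diveBinEdges(prog)) - 1
  tadcols <- grep("^tad_", colnames(d))
  dmdcols <- grep("^dmd_", colnames(d))
  if (length(tadcols) != nb || length(dmdcols) != nb)
    stop("bin-edge mismatch: file has ", length(tadcols),
         " TAD bins but dialect '", prog, "' expects ", nb)
  ts <- .parseUTC(d$window_start)
  if (any(is.na(ts)))
    stop("malformed window_start at row(s) ",
         paste(utils::head(which(is.na(ts)), 5), collapse = ", "))
  d$window_start <- ts
  bad <- which(abs(rowSums(d[, tadcols]) - 100) > 0.5)
  if (length(bad)) stop("TAD does not sum to 100% at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(d[, dmdcols] < 0) || any(d[, dmdcols] != round(d[, dmdcols])))
    stop("DMD counts must be non-negative integers")
  d
}

#' @rdname readDiveBins
#' @param divebins Data.frame as produced by [degradeToArgos()].
#' @export
writeDiveBins <- function(divebins, path) {
  d <- divebins
  d$window_start <- format(d$window_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read and write rasters as ESRI ASCII grid
#'
#' Plain-text raster interchange (`.asc`): a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from the
#' top. Matrices here are stored south-up, so rows are flipped on the way
#' in and out.
#'
#' @param path `.asc` file path.
#' @return `readAsciiGrid`: list with `data` (matrix, south-up), `origin`,
#'   `res`.
#' @export
readAsciiGrid <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, col.names = c("key", "value"),
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(as.numeric(hdr$value), tolower(hdr$key))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals["nrows"], ncol(m) == vals["ncols"])
  m[m == vals["nodata_value"]] <- NA
  list(data = m[nrow(m):1, , drop = FALSE],
       origin = unname(vals[c("xllcorner", "yllcorner")]),
       res = unname(vals["cellsize"]))
}

#' @rdname readAsciiGrid
#' @param data Numeric matrix (south-up rows).
#' @param origin Lower-left corner `c(x, y)`.
#' @param res Cell size.
#' @param nodata Value written for NA cells.
#' @export
writeAsciiGrid <- function(data, path, origin = c(0, 0), res = 1,
                           nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(data)),
    paste("nrows", nrow(data)),
    paste("xllcorner", origin[1]),
    paste("yllcorner", origin[2]),
    paste("cellsize", res),
    paste("NODATA_value", nodata)), con)
  m <- data[nrow(data):1, , drop = FALSE]
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize fitted HMM parameters to JSON
#'
#' Writes the full parameter object (emission coefficient vectors keyed
#' stream/state/parameter, zero-mass logits, transition coefficients and
#' the covariate standardization) so a fit can be reloaded and applied to
#' new data.
#'
#' @param fit An [fitHMM()] object (or a bare params list).
#' @param path Output JSON path.
#' @export
writeHMMParams <- function(fit, path) {
  obj <- if (inherits(fit, "hmmFit"))
    list(params = fit$params, covScale = fit$covScale,
         loglik = fit$loglik, npar = fit$npar)
  else list(params = fit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeHMMParams
#' @export
readHMMParams <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  for (s in names(p$emission)) {
    p$emission[[s]]$beta1 <- lapply(p$emission[[s]]$beta1, as.numeric)
    p$emission[[s]]$beta2 <- lapply(p$emission[[s]]$beta2, as.numeric)
    if (!is.null(p$emission[[s]]$zeta))
      p$emission[[s]]$zeta <- as.numeric(p$emission[[s]]$zeta)
  }
  p$trans_beta <- as.matrix(p$trans_beta)
  obj$params <- p
  obj
}

#' Read and write a simulation configuration as YAML
#'
#' Serializes a [simConfig()] (matrices as row lists, timestamps as
#' ISO-8601 strings) so simulated datasets are reproducible from a config
#' file plus a seed. Covariate-dependent transition specs (coefficient
#' lists) are serialized with their formula deparsed.
#'
#' @param config A [simConfig()].
#' @param path YAML file path.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(inherits(config, "simConfig"))
  obj <- unclass(config)
  obj$start_date <- format(config$start_date, "%Y-%m-%dT%H:%M:%S",
                           tz = "UTC")
  if (is.matrix(obj$transition_spec)) {
    obj$transition_spec <- list(type = "matrix",
                                rows = apply(obj$transition_spec, 1,
                                             as.numeric, simplify = FALSE))
  } else {
    obj$transition_spec <- list(
      type = "logit", formula = deparse(obj$transition_spec$formula),
      beta = apply(obj$transition_spec$beta, 1, as.numeric,
                   simplify = FALSE))
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  ts <- obj$transition_spec
  trans <- if (identical(ts$type, "matrix")) {
    do.call(rbind, ts$rows)
  } else {
    list(formula = stats::as.formula(ts$formula),
         beta = do.call(rbind, ts$beta))
  }
  ep <- lapply(obj$state_emission_params, function(e) lapply(e, as.numeric))
  simConfig(n_animals = obj$n_animals,
            n_steps_per_animal = obj$n_steps_per_animal,
            state_emission_params = ep,
            transition_spec = trans,
            duty_cycle_days = obj$duty_cycle_days,
            dropout_prob = obj$dropout_prob,
            dropout_mean_days = obj$dropout_mean_days,
            argos_smaj_km = obj$argos_smaj_km,
            argos_smin_km = obj$argos_smin_km,
            prog = obj$prog,
            start_date = .parseUTC(obj$start_date),
            seed = obj$seed)
}

#' Read and write a pipeline configuration
#'
#' YAML round-trip of the analysis thresholds (speed filter, gap threshold,
#' covariate buffer, stream boundaries, cell size, masking counts, timezone
#' offset, dive-window anchor, seed, optimizer starts).
#'
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- defaultPipelineConfig()
  out <- utils::modifyList(defaults, cfg)
  .validatePipelineConfig(out)
  out
}

#' @rdname readPipelineConfig
#' @param config Named list of settings.
#' @export
writePipelineConfig <- function(config, path) {
  .validatePipelineConfig(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readPipelineConfig
#' @export
defaultPipelineConfig <- function() {
  list(max_speed_ms = 10, gap_days = 7, buffer_km = 20,
       surface_m = 6, deep_m = 400, cell_km = 50,
       min_plot = 4, min_confident = 16,
       tz_offset_h = -4, window_anchor_h = 3,
       interval_h = 2, seed = 1, n_starts = 10)
}

.validatePipelineConfig <- function(cfg) {
  pos <- c("max_speed_ms", "gap_days", "buffer_km", "surface_m", "deep_m",
           "cell_km", "min_plot", "min_confident", "interval_h", "n_starts")
  for (f in pos)
    if (is.null(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field ", f, " must be positive")
  invisible(cfg)
}
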