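#' Run the full analysis pipeline on simulated data
#'
#' End-to-end driver chaining every stage on a synthetic dataset:
#' simulation, location cleaning, gap segmentation, CTCRW fitting and
#' regular prediction, stream/covariate construction, HMM fitting, Viterbi
#' decoding, and spatial summaries. Primarily a smoke-test and worked
#' example; real analyses call the stages individually.
#'
#' @param config A [simConfig()] for the data generator.
#' @param pipeline A pipeline configuration list (see
#'   [defaultPipelineConfig()]).
#' @param spec An [hmmSpec()]; default [interceptOnlySpec()] keeps the
#'   smoke-test fit small.
#' @param out_dir Optional directory; when given, decoded steps (CSV),
#'   fitted parameters (JSON) and the disproportionate-state grid (ASCII
#'   raster) are written there.
#' @return List with `steps` (decoded StepRecords), `fit`, `budget`,
#'   `cells` and `sprime`.
#' @export
runPipeline <- function(config = simConfig(n_animals = 3,
                                           n_steps_per_animal = 250),
                        pipeline = defaultPipelineConfig(),
                        spec = interceptOnlySpec(),
                        out_dir = NULL) {
  sim <- simulateDataset(config)
  env <- sim$env

  locs <- cleanLocations(sim$locations, max_speed = pipeline$max_speed_ms,
                         env = env)
  locs <- segmentTrack(locs, gap_days = pipeline$gap_days)
  xy <- projectAEQD(locs$lon, locs$lat, env$center)
  locs$x <- xy$x; locs$y <- xy$y

  preds <- list()
  for (id in unique(locs$animal_id)) {
    fit_c <- fitCTCRW(locs[locs$animal_id == id, ], n_starts = 2,
                      seed = config$seed)
    preds[[id]] <- predictRegular(fit_c, interval_h = pipeline$interval_h,
                                  anchor_h = pipeline$window_anchor_h)
  }
  pred <- do.call(rbind, preds)
  ext <- envExtent(env)
  pred$x <- pmin(pmax(pred$x, ext["xmin"] + 1e-6), ext["xmax"] - 1e-6)
  pred$y <- pmin(pmax(pred$y, ext["ymin"] + 1e-6), ext["ymax"] - 1e-6)

  steps <- buildSteps(pred, sim$divebins, env, prog = config$prog,
                      interval_h = pipeline$interval_h)
  fit <- fitHMM(steps, spec = spec, n_starts = min(pipeline$n_starts, 3),
                seed = pipeline$seed)
  steps$state <- fit$states
  budget <- stateTimeBudget(fit$states)
  cells <- rasterizeStates(steps$x, steps$y, steps$state,
                           cell_km = pipeline$cell_km)
  sp <- disproportionateState(cells, min_plot = pipeline$min_plot,
                              min_confident = pipeline$min_confident)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(steps, file.path(out_dir, "decoded_steps.csv"),
                     row.names = FALSE)
    writeHMMParams(fit, file.path(out_dir, "hmm_params.json"))
    writeAsciiGrid(sp$sprime, file.path(out_dir, "sprime.asc"),
                   origin = cells$origin, res = cells$cell_km)
  }
  list(steps = steps, fit = fit, budget = budget, cells = cells,
       sprime = sp)
}
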