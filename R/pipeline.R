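# Orchestration: validated run configurations, deterministic pipeline
# commands, structured logging, and recovery reports.

RUN_CONFIG_KEYS <- c("seed", "outdir", "scene", "plate", "imgproc",
                     "polarization", "redoxstats", "bulkassays", "experiment",
                     "verbosity")

#' Default run configuration
#'
#' A fully serializable nested list holding the seed and per-module parameter
#' blocks. A copy of the active configuration (with its hash) is written next
#' to every run's outputs.
#'
#' @param seed root seed for all randomness.
#' @param outdir output directory.
#' @param ... overrides for the top-level blocks (unknown keys are an error).
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("retquant_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    scene = unclass(scene_config(seed = seed)),
    plate = list(n_wells_per_conc = 3, concentrations_nM = c(0, 10, 30, 100,
                                                             300, 1000, 3000),
                 noise_sigma = 2),
    imgproc = list(percentile = 50, dilation_px = 3, wiener_kernel_px = 5,
                   grid_spacing_px = 16, levels = 3, qc_threshold = 0.6),
    polarization = list(gm_mv = -30, g3p_mv = 20),
    redoxstats = list(bin_width = 0.05, eps = 1, k = 2, c_mult = 2,
                      n_cells = 100, n_mock = 20, masked_fraction = 0.064),
    bulkassays = list(cycle_window = c(5, 18)),
    experiment = "masked-ret",
    verbosity = 1)
  dots <- list(...)
  bad <- setdiff(names(dots), RUN_CONFIG_KEYS)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(dots)) {
    if (is.list(cfg[[k]]) && is.list(dots[[k]])) {
      badsub <- setdiff(names(dots[[k]]), names(cfg[[k]]))
      if (length(badsub)) stop("unknown config key(s): ",
                               paste(paste0(k, "$", badsub), collapse = ", "))
      cfg[[k]][names(dots[[k]])] <- dots[[k]]
    } else cfg[[k]] <- dots[[k]]
  }
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  bad <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

log_jsonl <- function(path, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10), "\n",
      file = path, append = TRUE, sep = "")
}

write_config_copy <- function(config, outdir) {
  cfg <- unclass(config)
  cfg$config_hash <- config_hash(cfg)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  cfg$config_hash
}

#' Run a pipeline command
#'
#' Commands: `simulate` writes a synthetic scene (TIFF + truth JSON) and a
#' plate table (CSV); `analyze-mito` runs the glass-arm direction analysis;
#' `analyze-cells` runs the cell-arm reverse-transport fraction estimator;
#' `analyze-plate` extracts rates, calibrates them and fits the
#' dose-response; `recover` runs the named recovery experiment (currently
#' `masked-ret`) and writes a recovery report pairing every estimate with its
#' generator truth. All outputs are plain formats (TIFF/CSV/JSON/YAML), every
#' run writes its config copy and hash, and a JSON-lines log records
#' per-stage timing.
#'
#' @param command one of `simulate`, `analyze-mito`, `analyze-cells`,
#'   `analyze-plate`, `recover`.
#' @param config a [run_config()].
#' @return the command's result, invisibly; artifacts on disk under
#'   `config$outdir`.
#' @export
run_pipeline <- function(command = c("simulate", "analyze-mito",
                                     "analyze-cells", "analyze-plate",
                                     "recover"),
                         config = run_config()) {
  command <- match.arg(command)
  validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- write_config_copy(config, config$outdir)
  logf <- file.path(config$outdir, "run.log.jsonl")
  t0 <- proc.time()[[3]]
  scfg <- do.call(scene_config, config$scene[setdiff(names(config$scene),
                                                     "min_separation")])
  result <- switch(
    command,
    "simulate" = {
      scene <- build_scene(scfg)
      stack <- render_frames(scene, c("baseline", "challenge"),
                             channel = "nadph", challenged = c(FALSE, TRUE))
      write_frame_stack(stack, file.path(config$outdir, "nadph.tiff"))
      plate <- simulate_plate(default_plate_truth(config))
      utils::write.csv(cbind(plate, config_hash = hash),
                       file.path(config$outdir, "plate.csv"),
                       row.names = FALSE)
      list(scene = scene, plate = plate)
    },
    "analyze-mito" = {
      ex <- direction_experiment(n_fields = 4, seed = config$seed,
                                 config = glass_config(seed = config$seed),
                                 c_mult = config$redoxstats$c_mult)
      out <- ex$calls$fractions
      out$config_hash <- hash
      utils::write.csv(out, file.path(config$outdir, "direction_fractions.csv"),
                       row.names = FALSE)
      ex
    },
    "analyze-cells" = {
      rs <- config$redoxstats
      ex <- ret_fraction_experiment(n_cells = rs$n_cells, n_mock = rs$n_mock,
                                    masked_fraction = rs$masked_fraction,
                                    seed = config$seed, config = scfg,
                                    k = rs$k, bin_width = rs$bin_width)
      jsonlite::write_json(list(pooled_mean = ex$pooled$pooled_mean,
                                pooled_se = ex$pooled$pooled_se,
                                sigma0 = ex$null$sigma0,
                                n_used = ex$n_used, config_hash = hash),
                           file.path(config$outdir, "ret_fraction.json"),
                           auto_unbox = TRUE, digits = NA)
      ex
    },
    "analyze-plate" = {
      plate <- simulate_plate(default_plate_truth(config))
      rates <- do.call(rbind, lapply(split(plate, plate$well), function(w) {
        r <- fit_rate(w, config$bulkassays$cycle_window)
        data.frame(well = w$well[1], role = w$role[1],
                   s1qel_concentration = w$s1qel_concentration[1],
                   slope_afu_min = r$slope)
      }))
      smp <- rates[rates$role == "sample", ]
      fit <- fit_4pl(smp$s1qel_concentration, smp$slope_afu_min)
      rates$config_hash <- hash
      utils::write.csv(rates, file.path(config$outdir, "rates.csv"),
                       row.names = FALSE)
      jsonlite::write_json(c(as.list(coef(fit)), list(config_hash = hash)),
                           file.path(config$outdir, "fit_4pl.json"),
                           auto_unbox = TRUE, digits = NA)
      list(rates = rates, fit = fit)
    },
    "recover" = {
      if (!identical(config$experiment, "masked-ret"))
        stop("unknown experiment: ", config$experiment)
      rs <- config$redoxstats
      ex <- ret_fraction_experiment(n_cells = rs$n_cells, n_mock = rs$n_mock,
                                    masked_fraction = rs$masked_fraction,
                                    seed = config$seed, config = scfg,
                                    k = rs$k, bin_width = rs$bin_width)
      report <- list(experiment = "masked-ret",
                     truth = rs$masked_fraction,
                     estimate = ex$pooled$pooled_mean,
                     se = ex$pooled$pooled_se,
                     tolerance = c(lower = 0.04, upper = rs$masked_fraction),
                     pass = ex$pooled$pooled_mean >= 0.04 &&
                       ex$pooled$pooled_mean <= rs$masked_fraction,
                     n_cells = ex$n_used,
                     runtime_s = proc.time()[[3]] - t0,
                     config_hash = hash)
      jsonlite::write_json(report, file.path(config$outdir, "recovery_report.json"),
                           auto_unbox = TRUE, digits = NA)
      structure(report, class = "recovery_report")
    })
  log_jsonl(logf, command, seconds = round(proc.time()[[3]] - t0, 3),
            config_hash = hash)
  invisible(result)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("Recovery report (%s): truth %.3f, estimate %.4f",
                     " +/- %.4f over %d cells -> %s\n"),
              x$experiment, x$truth, x$estimate, x$se %||% NA, x$n_cells,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

## The plate layout used by simulate / analyze-plate: triplicate sample wells
## across the configured titration, matched cell-free backgrounds, vehicle
## wells and one calibration well.
default_plate_truth <- function(config) {
  pc <- config$plate
  concs <- rep(pc$concentrations_nM, each = pc$n_wells_per_conc)
  wells <- data.frame(
    well = c(sprintf("S%02d", seq_along(concs)),
             sprintf("B%02d", seq_along(concs)),
             "V01", "V02", "V03", "C01"),
    role = c(rep("sample", length(concs)),
             rep("cell_free_background", length(concs)),
             rep("vehicle", 3), "calibration"),
    condition = c(paste0("s1qel_", concs), paste0("bg_", concs),
                  rep("vehicle", 3), "calibration"),
    true_h2o2_rate = c(rep(NA_real_, 2 * length(concs)), rep(NA_real_, 3), NA),
    background_rate = c(rep(5, 2 * length(concs)), rep(5, 3), 0),
    s1qel_concentration = c(concs, concs, 0, 0, 0, NA),
    stringsAsFactors = FALSE)
  plate_truth(wells, noise_sigma = pc$noise_sigma, seed = config$seed)
}
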