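# Pipeline orchestration: config loading, per-condition reports, map bundle,
# report serialisation.

#' Read a run configuration
#'
#' Loads a JSON or YAML configuration describing the fluid/nozzle parameters,
#' per-condition input files and threshold overrides. Referenced files are
#' checked for existence.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list of class `"run_config"` with elements `constants`,
#'   `nozzle`, `conditions` and (optionally) `thresholds`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  for (blk in c("nozzle", "conditions")) {
    if (is.null(cfg[[blk]])) stop("config is missing the '", blk, "' block",
                                  call. = FALSE)
  }
  if (is.null(cfg$constants$g)) cfg$constants <- list(g = 9.80665)
  for (cond in cfg$conditions) {
    for (f in intersect(names(cond),
                        c("flow_curve", "displacement", "bursts"))) {
      if (!file.exists(cond[[f]])) {
        stop("condition '", cond$name, "': file not found: ", cond[[f]],
             call. = FALSE)
      }
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

.default_thresholds <- function() {
  list(splash_threshold = 57.7, alpha = 2, shear_floor = 1e-2,
       cv_max = 5, r2_min = 0.99)
}

#' Run the full printability pipeline
#'
#' For each configured condition: fits the power-law viscosity model to the
#' flow curve, estimates the jet velocity from the displacement sweep,
#' calibrates the per-drop volume gravimetrically, computes the
#' dimensionless jetting numbers and the nozzle flow profile, and classifies
#' the regime. A failure in one condition is recorded (with the failing
#' stage named) without stopping the others.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @return A list of class `"printability_run"`: `reports` (one tibble row
#'   per condition, `failed`/`failed_stage` columns for failures), `maps`
#'   (named list of `printability_map` objects for the planes whose
#'   coordinates are available), `thresholds`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  thr <- utils::modifyList(.default_thresholds(),
                           config$thresholds %||% list())
  constants <- physical_constants(config$constants$g)
  nz <- config$nozzle

  reports <- purrr::map_dfr(config$conditions, function(cond) {
    stage <- "init"
    tryCatch({
      base <- tibble::tibble(name = cond$name,
                             density = cond$density,
                             surface_tension = cond$surface_tension,
                             t20 = cond$t20 %||% 0,
                             cell_density = cond$cell_density %||% 0)
      fit <- NULL
      if (!is.null(cond$flow_curve)) {
        stage <- "rheology"
        fc <- read_flow_curve(cond$flow_curve)
        fit <- fit_power_law(fc)
        base$consistency_index <- fit$consistency_index
        base$flow_index <- fit$flow_index
        base$fit_converged <- fit$converged
      }
      stage <- "velocity"
      vel <- estimate_velocity(readr::read_csv(cond$displacement,
                                               show_col_types = FALSE))
      stage <- "calibration"
      cal <- calibrate_drop_volume(
        readr::read_csv(cond$bursts, show_col_types = FALSE),
        density = cond$density, cv_max = thr$cv_max, r2_min = thr$r2_min)
      stage <- "dimensionless"
      din <- tibble::tibble(density = cond$density,
                            surface_tension = cond$surface_tension,
                            velocity = vel$velocity,
                            diameter = nz$diameter_m)
      if (!is.null(cond$viscosity)) din$viscosity <- cond$viscosity
      dn <- dimensionless_numbers(din, fit = fit, constants = constants)
      stage <- "nozzle_flow"
      Q <- flow_rate_from_ligament(cal$per_drop_volume, nz$dwell_s)
      prof <- nozzle_flow_profile(
        Q, radius = nz$radius_m,
        flow_index = if (is.null(fit)) 1 else fit$flow_index,
        consistency_index = if (is.null(fit)) NULL
                            else fit$consistency_index,
        floor = thr$shear_floor, length = nz$length_m %||% 0.84e-3)
      stage <- "regimes"
      lab <- classify_regimes(dn, splash_threshold = thr$splash_threshold)
      metrics <- ligament_metrics(cal$per_drop_volume, vel$velocity,
                                  nz$diameter_m,
                                  length = cond$ligament_length %||%
                                    NA_real_)
      dplyr::bind_cols(
        base,
        dplyr::select(lab, -dplyr::any_of(names(base))),
        tibble::tibble(
          velocity_se = vel$se,
          per_drop_volume = cal$per_drop_volume,
          calibration_cv = cal$cv,
          calibration_r2 = cal$linearity_r2,
          calibration_accepted = cal$accepted,
          ligament_length = metrics$length,
          l_ar = metrics$aspect_ratio,
          equivalent_diameter = metrics$equivalent_diameter,
          flow_rate = Q,
          wall_shear_rate = attr(prof, "wall_shear_rate"),
          wall_viscosity = attr(prof, "wall_viscosity"),
          contact_angle = cond$contact_angle %||% NA_real_,
          failed = FALSE, failed_stage = NA_character_)
      )
    }, error = function(e) {
      tibble::tibble(name = cond$name, failed = TRUE, failed_stage = stage,
                     error = conditionMessage(e))
    })
  })

  ok <- reports[!reports$failed, , drop = FALSE]
  maps <- list()
  if (nrow(ok) > 0) {
    for (mt in c("We_Fr", "We_Oh", "We_Re", "Oh_Re")) {
      maps[[mt]] <- build_map(ok, mt)
    }
    if (any(is.finite(ok$l_ar))) maps[["Lar_Oh"]] <- build_map(ok, "Lar_Oh")
  }
  structure(list(reports = reports, maps = maps, thresholds = thr),
            class = "printability_run")
}

#' @export
print.printability_run <- function(x, ...) {
  cat("Printability run:", nrow(x$reports), "condition(s),",
      sum(x$reports$failed), "failed;", length(x$maps), "map(s)\n")
  invisible(x)
}

#' Write condition reports to disk
#'
#' JSON output is a lossless round trip of the report table; CSV flattens it
#' with a stable column order.
#'
#' @param reports Report tibble (e.g. `run$reports`).
#' @param path Output file path; the directory must exist.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, format = c("json", "csv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  if (format == "json") {
    jsonlite::write_json(reports, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(reports[, sort(names(reports))], path, na = "")
  }
  invisible(path)
}

#' Read back a JSON condition report
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return The report tibble.
#' @export
read_report <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
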