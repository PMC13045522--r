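# Seeded synthetic-data generators.  Each generator is a pure function of
# (parameters, seed) and its output passes the corresponding loader's
# validation, so the full pipeline is testable with no external data.

#' Generate a synthetic flow curve
#'
#' Emulates a steady-shear rheometer sweep of a power-law fluid: apparent
#' viscosity K·γ̇^(n−1) on a log-spaced shear-rate grid, optionally corrupted
#' by multiplicative lognormal or additive Gaussian noise.
#'
#' @param K Consistency index, Pa·sⁿ (> 0).
#' @param n Flow index, ∈ (0.05, 1.5].
#' @param seed Integer seed; fixed seed gives identical output.
#' @param n_points Number of grid points.
#' @param shear_range Two-element range of shear rates (1/s); log-spaced.
#' @param noise `"none"`, `"multiplicative_lognormal"` or
#'   `"additive_gaussian"`.
#' @param noise_level Relative noise SD (fraction, e.g. 0.01 for 1%).
#' @param direction Sweep direction label.
#' @param formulation Optional one-row tibble from [formulation()].
#' @return A `flow_curve` tibble (see [flow_curve()]).
#' @export
gen_flow_curve <- function(K, n, seed = 1, n_points = 30,
                           shear_range = c(0.1, 1000),
                           noise = c("none", "multiplicative_lognormal",
                                     "additive_gaussian"),
                           noise_level = 0, direction = "up",
                           formulation = NULL) {
  noise <- match.arg(noise)
  stopifnot(K > 0, n > 0.05, n <= 1.5, n_points >= 5,
            all(shear_range > 0), noise_level >= 0)
  g <- 10^seq(log10(shear_range[1]), log10(shear_range[2]),
              length.out = n_points)
  mu <- K * g^(n - 1)
  if (noise != "none" && noise_level > 0) {
    mu <- withr::with_seed(seed, {
      eps <- stats::rnorm(n_points, 0, noise_level)
      switch(noise,
             multiplicative_lognormal = mu * exp(eps),
             additive_gaussian = pmax(mu * (1 + eps), .Machine$double.eps))
    })
  }
  flow_curve(
    tibble::tibble(shear_rate_1_per_s = g, viscosity_Pa_s = mu),
    direction = direction, formulation = formulation
  )
}

#' Generate a synthetic ligament displacement sweep
#'
#' Emulates stroboscopic leading-edge tracking: position = v·t plus Gaussian
#' jitter, sampled at fixed frame increments (default 50 µs).
#'
#' @param v True jet velocity, m/s (⩾ 0).
#' @param seed Integer seed.
#' @param frames Number of frames (⩾ 3).
#' @param frame_dt Frame time increment, s.
#' @param jitter_sd Gaussian position-jitter SD, m.
#' @return Tibble with `time` (s) and `position` (m).
#' @export
gen_displacement <- function(v, seed = 1, frames = 37, frame_dt = 50e-6,
                             jitter_sd = 0) {
  stopifnot(v >= 0, frames >= 3, frame_dt > 0, jitter_sd >= 0)
  t <- frame_dt * seq_len(frames)
  x <- v * t
  if (jitter_sd > 0) {
    x <- x + withr::with_seed(seed, stats::rnorm(frames, 0, jitter_sd))
  }
  tibble::tibble(time = t, position = x)
}

#' Generate a synthetic gravimetric calibration series
#'
#' Emulates burst-mode drop collection: per-burst net mass =
#' drops · ρ · (V + slope·(dwell − dwell₀)) · (1 + noise), with relative
#' noise SD equal to the requested coefficient of variation. Bursts are
#' generated at the operating dwell plus any additional dwell times listed,
#' so the volume-vs-dwell linearity check is exercised.
#'
#' @param V Per-drop volume at the operating dwell, m³.
#' @param density Solution density, kg/m³.
#' @param cv Coefficient of variation of burst masses, percent.
#' @param seed Integer seed.
#' @param bursts Replicate bursts per dwell time.
#' @param drops Droplets per burst.
#' @param dwell_set Dwell times, s; the first is the operating dwell.
#' @param slope Volume sensitivity to dwell, m³/s.
#' @return Tibble with `dwell` (s), `drops`, `mass` (kg).
#' @export
gen_drop_masses <- function(V, density, cv = 0, seed = 1, bursts = 3,
                            drops = 1000,
                            dwell_set = c(1000e-6, 900e-6, 1100e-6),
                            slope = 0) {
  stopifnot(V > 0, density > 0, cv >= 0, bursts >= 1, drops >= 1,
            all(dwell_set > 0))
  grid <- tidyr::expand_grid(dwell = dwell_set, rep = seq_len(bursts))
  vol <- V + slope * (grid$dwell - dwell_set[1])
  mass <- drops * density * vol
  if (cv > 0) {
    mass <- mass * withr::with_seed(
      seed, 1 + stats::rnorm(nrow(grid), 0, cv / 100))
  }
  tibble::tibble(dwell = grid$dwell, drops = drops, mass = mass)
}

#' Write a complete synthetic fixture bundle
#'
#' Writes flow-curve, displacement and burst-mass CSVs (in the dialects the
#' loaders expect) plus a JSON condition config into a directory, so the
#' whole pipeline can run end to end from generated files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param conditions Tibble of conditions; default is a small two-ink set.
#' @return Invisibly, a tibble of the files written per condition.
#' @export
write_synth_bundle <- function(dir, seed = 1, conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- tibble::tibble(
      name = c("fibrinogen_5", "agarose_0.7_t20"),
      K = c(1.1e-3, 0.35),
      n = c(0.98, 0.22),
      density = c(1000, 1005),
      surface_tension = c(0.054, 0.040),
      velocity = c(4.77, 1.3),
      volume = c(60e-12, 30e-12)
    )
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::pmap_dfr(conditions, function(name, K, n, density,
                                                surface_tension, velocity,
                                                volume, ...) {
    s <- seed + match(name, conditions$name)
    fc <- gen_flow_curve(K, n, seed = s, noise = "multiplicative_lognormal",
                         noise_level = 0.01)
    disp <- gen_displacement(velocity, seed = s, jitter_sd = 10e-6)
    masses <- gen_drop_masses(volume, density, cv = 1, seed = s,
                              slope = volume / 20e-3)
    fc_path <- file.path(dir, paste0(name, "_flow_curve.csv"))
    disp_path <- file.path(dir, paste0(name, "_displacement.csv"))
    mass_path <- file.path(dir, paste0(name, "_bursts.csv"))
    readr::write_csv(tibble::tibble(shear_rate_1_per_s = fc$shear_rate,
                                    viscosity_Pa_s = fc$viscosity), fc_path)
    readr::write_csv(disp, disp_path)
    readr::write_csv(masses, mass_path)
    tibble::tibble(name = name, flow_curve = fc_path,
                   displacement = disp_path, bursts = mass_path)
  })
  cfg <- list(
    constants = list(g = 9.80665),
    nozzle = list(diameter_m = 2.5e-4, radius_m = 1.25e-4,
                  length_m = 8.4e-4, dwell_s = 1e-3, frequency_hz = 200),
    conditions = purrr::pmap(
      dplyr::left_join(conditions, files, by = "name"),
      function(name, density, surface_tension, flow_curve, displacement,
               bursts, ...) {
        list(name = name, density = density,
             surface_tension = surface_tension,
             flow_curve = flow_curve, displacement = displacement,
             bursts = bursts)
      })
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
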