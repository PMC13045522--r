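# Dimensionless jetting analysis.
#
# Definitions (D = nozzle orifice diameter, v = measured ligament velocity):
#   We = rho v^2 D / sigma      inertia vs capillarity
#   Re = rho v D / mu           inertia vs viscous dissipation
#   Oh = mu / sqrt(rho sigma D) = sqrt(We)/Re
#   Fr = v / sqrt(g D)          inertia vs gravity
#   Z  = 1/Oh                   canonical printable band 1 <= Z <= 10
#   K_splash = Oh * Re^1.25     Mundo-type impact/splash composite
#   Bo = We / Fr^2 = rho g D^2 / sigma

#' Dimensionless jetting numbers for a table of conditions
#'
#' Computes Weber, Reynolds, Ohnesorge, Froude, Z = 1/Oh, the splash
#' parameter Oh·Re^1.25 and the Bond number for each row of a condition
#' table. The characteristic length is the nozzle orifice diameter and the
#' characteristic velocity the measured ligament velocity. The characteristic
#' viscosity may be given directly (`viscosity` column) or derived from a
#' power-law fit evaluated at a characteristic shear rate (default v/D), in
#' which case `fit` is supplied and the selection path recorded.
#'
#' @param data Data frame with columns `density` (kg/m³), `surface_tension`
#'   (N/m), `velocity` (m/s), `diameter` (m), and either `viscosity` (Pa·s)
#'   or a `fit` supplied separately.
#' @param fit Optional `power_law_fit` used to derive the characteristic
#'   viscosity at `char_shear_rate` when `data` lacks a `viscosity` column.
#' @param char_shear_rate Characteristic shear rate (1/s) for the power-law
#'   path; default `velocity / diameter` row-wise.
#' @param constants A [physical_constants()] object.
#' @return `data` with columns `viscosity` (filled if derived), `we`, `re`,
#'   `oh`, `fr`, `z`, `k_splash`, `bond` appended; attribute
#'   `viscosity_source` records which path supplied viscosity.
#' @examples
#' tibble::tibble(density = 1000, surface_tension = 0.0539,
#'                viscosity = 1e-3, velocity = 4.77, diameter = 2.5e-4) |>
#'   dimensionless_numbers()
#' @export
dimensionless_numbers <- function(data, fit = NULL, char_shear_rate = NULL,
                                  constants = physical_constants()) {
  stopifnot(is.data.frame(data),
            all(c("density", "surface_tension", "velocity", "diameter")
                %in% names(data)))
  data <- tibble::as_tibble(data)
  source <- "measured"
  if (!"viscosity" %in% names(data) || all(is.na(data$viscosity))) {
    if (is.null(fit)) {
      stop("supply either a 'viscosity' column or a power-law 'fit'",
           call. = FALSE)
    }
    gc <- if (is.null(char_shear_rate)) data$velocity / data$diameter
          else char_shear_rate
    data$viscosity <- apparent_viscosity(fit, gc)
    source <- "power_law_at_char_shear"
  }
  with_cols <- dplyr::mutate(
    data,
    we = .data$density * .data$velocity^2 * .data$diameter /
      .data$surface_tension,
    re = .data$density * .data$velocity * .data$diameter / .data$viscosity,
    oh = .data$viscosity /
      sqrt(.data$density * .data$surface_tension * .data$diameter),
    fr = .data$velocity / sqrt(constants$g * .data$diameter),
    z = 1 / .data$oh,
    k_splash = .data$oh * .data$re^1.25,
    bond = .data$we / .data$fr^2
  )
  # definitional identity Oh = sqrt(We)/Re must hold to round-off
  stopifnot(all(abs(with_cols$oh - sqrt(with_cols$we) / with_cols$re) <=
                  1e-12 * with_cols$oh))
  attr(with_cols, "viscosity_source") <- source
  with_cols
}

#' Ohnesorge number from Weber and Reynolds numbers
#'
#' The identity Oh = √We / Re lets Oh be recovered from a published (We, Re)
#' pair without knowing the underlying fluid properties.
#'
#' @param we,re Positive Weber and Reynolds numbers (vectorised).
#' @return Ohnesorge number(s).
#' @examples
#' oh_from_we_re(105.39, 1191.5) # ~0.0086
#' @export
oh_from_we_re <- function(we, re) {
  stopifnot(all(we > 0), all(re > 0))
  sqrt(we) / re
}

#' Splash parameter
#'
#' The Mundo-type impact composite K = Oh · Re^1.25. High values indicate
#' spreading and potential splashing on impact; low values contained
#' deposition.
#'
#' @param oh,re Positive Ohnesorge and Reynolds numbers (vectorised).
#' @return Splash parameter(s).
#' @export
splash_parameter <- function(oh, re) {
  stopifnot(all(oh > 0), all(re > 0))
  oh * re^1.25
}

#' Recover fluid properties from dimensionless numbers
#'
#' Closes the definition set: given (We, Re, Fr) with the density and nozzle
#' diameter, returns the jet velocity, surface tension and characteristic
#' viscosity that generate them. Forward recomputation through
#' [dimensionless_numbers()] reproduces the inputs.
#'
#' @param we,re,fr Positive dimensionless numbers (vectorised).
#' @param density Fluid density, kg/m³.
#' @param diameter Nozzle orifice diameter, m.
#' @param constants A [physical_constants()] object.
#' @return Tibble with `velocity` (m/s), `surface_tension` (N/m),
#'   `viscosity` (Pa·s).
#' @examples
#' invert_dimensionless(105.39, 1191.5, 96.278, density = 1000,
#'                      diameter = 2.5e-4)
#' @export
invert_dimensionless <- function(we, re, fr, density, diameter,
                                 constants = physical_constants()) {
  stopifnot(all(we > 0), all(re > 0), all(fr > 0),
            all(density > 0), all(diameter > 0))
  v <- fr * sqrt(constants$g * diameter)
  tibble::tibble(
    velocity = v,
    surface_tension = density * v^2 * diameter / we,
    viscosity = density * v * diameter / re
  )
}

#' Capillary (inertio-capillary) time scale
#'
#' τc = √(ρR³/σ), the natural time scale of capillary pinch-off for a
#' ligament of radius R; it bounds the achievable jetting frequency.
#'
#' @param density Fluid density, kg/m³.
#' @param surface_tension Surface tension, N/m.
#' @param radius Characteristic (nozzle) radius, m.
#' @return Capillary time in seconds.
#' @export
capillary_time <- function(density, surface_tension, radius) {
  stopifnot(all(density > 0), all(surface_tension > 0), all(radius >= 0))
  sqrt(density * radius^3 / surface_tension)
}

#' Viscosity-corrected pinch-off time and maximum jetting frequency
#'
#' The pinch-off time scales with the capillary time multiplied by a viscous
#' factor that grows with Oh: t_p = τc (1 + α·Oh). The reciprocal bounds the
#' drop-on-demand frequency; operational bands additionally clip it to the
#' valve's working window (see [recommend_frequency()]).
#'
#' @param tau_c Capillary time, s.
#' @param oh Ohnesorge number.
#' @param alpha Viscous-factor coefficient (dimensionless, ⩾ 0); default 2.
#' @return Tibble with `capillary_time`, `pinch_off_time` (s), `max_frequency`
#'   (Hz) and `alpha`.
#' @export
pinch_off_time <- function(tau_c, oh, alpha = 2) {
  stopifnot(all(tau_c > 0), all(oh >= 0), all(alpha >= 0))
  tp <- tau_c * (1 + alpha * oh)
  tibble::tibble(
    capillary_time = tau_c,
    pinch_off_time = tp,
    max_frequency = 1 / tp,
    alpha = alpha
  )
}

#' Read a dimensionless condition table
#'
#' Reads a CSV replicating the layout of a published per-condition summary
#' (formulation, concentration, surfactant flag, We, Re, Oh, Fr, ligament
#' length and aspect ratio), for regime classification and map plotting
#' without raw measurements. Missing Oh values are filled from √We/Re.
#'
#' @param path CSV path with columns `bioink`, `concentration`,
#'   `concentration_unit`, `t20`, `we`, `re`, and optionally `oh`, `fr`,
#'   `l_l_mm`, `l_ar`.
#' @return A tibble with `oh` and `z` guaranteed present.
#' @export
read_dimensionless_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("bioink", "we", "re")) {
    if (!col %in% names(tab)) {
      stop("dimensionless table is missing column '", col, "'",
           call. = FALSE)
    }
  }
  tab <- tibble::as_tibble(tab)
  if (!"oh" %in% names(tab)) tab$oh <- NA_real_
  # partially printed rows are allowed: fill Oh where (We, Re) exist,
  # propagate NA elsewhere
  tab$oh <- ifelse(is.na(tab$oh) & !is.na(tab$we) & !is.na(tab$re),
                   sqrt(tab$we) / tab$re, tab$oh)
  tab$z <- 1 / tab$oh
  tab$k_splash <- ifelse(!is.na(tab$oh) & !is.na(tab$re),
                         tab$oh * tab$re^1.25, NA_real_)
  tab
}
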