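# Shared quantity conventions: everything downstream of the loaders is SI.

# Exact rational scale factors to the SI base/derived unit of each quantity.
.si_scale <- c(
  "mPa.s"  = 1e-3,  # -> Pa.s
  "Pa.s"   = 1,
  "mN/m"   = 1e-3,  # -> N/m
  "N/m"    = 1,
  "um"     = 1e-6,  # -> m
  "mm"     = 1e-3,
  "m"      = 1,
  "nl"     = 1e-12, # -> m^3
  "ul"     = 1e-9,
  "m3"     = 1,
  "us"     = 1e-6,  # -> s
  "ms"     = 1e-3,
  "s"      = 1,
  "mg"     = 1e-6,  # -> kg
  "g"      = 1e-3,
  "kg"     = 1
)

# Tolerated spellings for the micro prefix and dotted/ASCII variants.
.si_alias <- c(
  "mPa·s" = "mPa.s", "Pa·s" = "Pa.s",
  "µm" = "um", "μm" = "um",
  "µl" = "ul", "μl" = "ul", "uL" = "ul", "µL" = "ul",
  "m³" = "m3",
  "µs" = "us", "μs" = "us"
)

.si_canon <- function(unit) {
  u <- as.character(unit)
  hit <- match(u, names(.si_alias))
  u[!is.na(hit)] <- .si_alias[hit[!is.na(hit)]]
  u
}

#' Convert a measured value to SI units
#'
#' Exact rational rescaling from a tagged laboratory unit to the corresponding
#' SI base or derived unit (viscosity to Pa·s, surface tension to N/m, length
#' to m, volume to m³, time to s, mass to kg). All package functions assume SI
#' inputs; this is the single place mixed units are resolved.
#'
#' @param value Numeric vector of measured values.
#' @param unit Unit tag, one of `si_units()`. Unicode micro signs and middle
#'   dots are accepted (e.g. `"µm"`, `"mPa·s"`).
#' @return Numeric vector in SI units.
#' @examples
#' convert_to_si(250, "um")   # 2.5e-4 m
#' convert_to_si(60, "nl")    # 6e-11 m^3
#' convert_to_si(1000, "us")  # 1e-3 s
#' @export
convert_to_si <- function(value, unit) {
  stopifnot(is.numeric(value), length(unit) == 1)
  u <- .si_canon(unit)
  if (!u %in% names(.si_scale)) {
    stop("unknown unit tag: '", unit, "' (supported: ",
         paste(names(.si_scale), collapse = ", "), ")", call. = FALSE)
  }
  value * .si_scale[[u]]
}

#' Convert an SI value back to a laboratory unit
#'
#' Inverse of [convert_to_si()]; used by the display layer to report in the
#' units conventional for this instrumentation (mPa·s, nl, mm, µs).
#'
#' @inheritParams convert_to_si
#' @param value Numeric vector in SI units.
#' @return Numeric vector in the requested unit.
#' @export
convert_from_si <- function(value, unit) {
  stopifnot(is.numeric(value), length(unit) == 1)
  u <- .si_canon(unit)
  if (!u %in% names(.si_scale)) {
    stop("unknown unit tag: '", unit, "'", call. = FALSE)
  }
  value / .si_scale[[u]]
}

#' Supported unit tags
#' @return Character vector of canonical unit tags accepted by
#'   [convert_to_si()].
#' @export
si_units <- function() names(.si_scale)

#' Physical constants
#'
#' @param g Gravitational acceleration in m/s²; enters the Froude number.
#' @return A list with class `"physical_constants"`.
#' @export
physical_constants <- function(g = 9.80665) {
  stopifnot(is.numeric(g), length(g) == 1, g > 0)
  structure(list(g = g), class = "physical_constants")
}

.bioinks <- c("fibrinogen", "collagen_I", "matrigel", "alginate",
              "agarose", "gelma", "other")
.conc_units <- c("mg/mL", "%w/v", "%v/v")

#' Describe a bioink formulation
#'
#' A formulation row carries the bioink identity and the covariates the
#' analysis conditions on: concentration (kept in its native unit -- mg/mL and
#' %w/v are never interconverted), the Tween 20 surfactant fraction, and the
#' encapsulated cell density.
#'
#' @param bioink One of `"fibrinogen"`, `"collagen_I"`, `"matrigel"`,
#'   `"alginate"`, `"agarose"`, `"gelma"`, `"other"`.
#' @param concentration Positive concentration in `concentration_unit`.
#' @param concentration_unit `"mg/mL"`, `"%w/v"` or `"%v/v"` -- an opaque
#'   label, never converted.
#' @param t20 Tween 20 volume fraction (%v/v); 0 if absent, at most 0.01.
#' @param cell_density Cells per mL; 0 for acellular inks.
#' @return One-row tibble.
#' @export
formulation <- function(bioink, concentration, concentration_unit,
                        t20 = 0, cell_density = 0) {
  bioink <- match.arg(bioink, .bioinks)
  concentration_unit <- match.arg(concentration_unit, .conc_units)
  stopifnot(concentration > 0, t20 >= 0, t20 <= 0.01, cell_density >= 0)
  tibble::tibble(
    bioink = bioink,
    concentration = concentration,
    concentration_unit = concentration_unit,
    t20 = t20,
    cell_density = cell_density
  )
}
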