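# Fully developed laminar power-law pipe flow in the nozzle.
#
# For a power-law fluid (mu = K g^(n-1)) in a circular tube of radius R at
# volumetric flow rate Q, the exact steady profile is
#   u(r)     = (Q / (pi R^2)) * ((3n+1)/(n+1)) * (1 - (r/R)^((n+1)/n))
#   gdot_w   = ((3n+1)/(4n)) * 4Q/(pi R^3)
#   gdot(r)  = gdot_w * (r/R)^(1/n)
# which reduces to classical Poiseuille flow at n = 1.  This closed form is
# the target solution of a stationary axisymmetric FE solve of the same
# problem, so no numerical PDE machinery is needed.

#' Volumetric flow rate from the ejected ligament
#'
#' Q = V_lig / dwell: the ejected ligament volume divided by the valve-open
#' (dwell) time, the mean flow rate through the nozzle during actuation.
#'
#' @param volume Ejected ligament volume, m³ (> 0).
#' @param dwell_time Valve dwell time, s (> 0).
#' @return Flow rate, m³/s.
#' @examples
#' flow_rate_from_ligament(60e-12, 1e-3) # 6e-8 m^3/s for 60 nl per 1 ms
#' @export
flow_rate_from_ligament <- function(volume, dwell_time) {
  stopifnot(all(volume > 0), all(dwell_time > 0))
  volume / dwell_time
}

#' Wall shear rate of power-law pipe flow
#'
#' γ̇_w = ((3n+1)/(4n)) · 4Q/(πR³); the Rabinowitsch–Mooney correction of the
#' Newtonian wall value.
#'
#' @param Q Volumetric flow rate, m³/s.
#' @param radius Tube radius, m.
#' @param flow_index Power-law flow index n ∈ (0.05, 1.5].
#' @return Wall shear rate, 1/s.
#' @export
wall_shear_rate <- function(Q, radius, flow_index) {
  stopifnot(all(Q > 0), all(radius > 0),
            all(flow_index > 0.05), all(flow_index <= 1.5))
  (3 * flow_index + 1) / (4 * flow_index) * 4 * Q / (pi * radius^3)
}

#' Radial flow profile inside the nozzle
#'
#' Evaluates the exact fully developed laminar power-law profile on a uniform
#' radial grid from the centreline to the wall: axial velocity, shear rate,
#' and (if a fit is given) apparent viscosity with the centreline
#' regularised by a shear-rate floor. No-slip holds exactly at the wall;
#' the velocity integrates back to Q.
#'
#' @param Q Volumetric flow rate, m³/s.
#' @param radius Nozzle internal radius, m.
#' @param flow_index Power-law flow index n ∈ (0.05, 1.5].
#' @param consistency_index Optional consistency index K (Pa·sⁿ); when given,
#'   an `apparent_viscosity` column is added.
#' @param grid_points Number of radial grid points (⩾ 16), endpoints
#'   included.
#' @param floor Shear-rate floor (1/s) regularising the centreline viscosity
#'   singularity for n < 1.
#' @param length Nozzle length, m (metadata only; the profile is fully
#'   developed and axially invariant).
#' @return A tibble of class `"nozzle_flow_profile"` with columns `r` (m),
#'   `velocity` (m/s), `shear_rate` (1/s) and optionally
#'   `apparent_viscosity` (Pa·s); attributes `Q`, `radius`, `length`,
#'   `flow_index`, `consistency_index`, `wall_shear_rate`, `wall_viscosity`.
#' @examples
#' prof <- nozzle_flow_profile(6e-8, radius = 1.25e-4, flow_index = 1,
#'                             consistency_index = 1e-3)
#' attr(prof, "wall_shear_rate") # ~3.9e4 1/s
#' @export
nozzle_flow_profile <- function(Q, radius, flow_index,
                                consistency_index = NULL,
                                grid_points = 256, floor = 1e-2,
                                length = 0.84e-3) {
  stopifnot(Q > 0, radius > 0, flow_index > 0.05, flow_index <= 1.5,
            grid_points >= 16, floor > 0, length > 0)
  n <- flow_index
  r <- seq(0, radius, length.out = grid_points)
  u_mean <- Q / (pi * radius^2)
  u <- u_mean * (3 * n + 1) / (n + 1) * (1 - (r / radius)^((n + 1) / n))
  u[grid_points] <- 0 # no-slip exact at the wall
  gw <- wall_shear_rate(Q, radius, n)
  g <- gw * (r / radius)^(1 / n)

  out <- tibble::tibble(r = r, velocity = u, shear_rate = g)
  wall_mu <- NA_real_
  if (!is.null(consistency_index)) {
    stopifnot(consistency_index > 0)
    fit <- list(consistency_index = consistency_index, flow_index = n)
    out$apparent_viscosity <- apparent_viscosity(fit, g, floor = floor)
    wall_mu <- apparent_viscosity(fit, gw, floor = floor)
  }
  attr(out, "Q") <- Q
  attr(out, "radius") <- radius
  attr(out, "length") <- length
  attr(out, "flow_index") <- n
  attr(out, "consistency_index") <-
    if (is.null(consistency_index)) NA_real_ else consistency_index
  attr(out, "wall_shear_rate") <- gw
  attr(out, "wall_viscosity") <- wall_mu
  class(out) <- c("nozzle_flow_profile", class(out))
  out
}

#' One-row wall summary of a nozzle flow profile
#'
#' @param x A `nozzle_flow_profile`.
#' @param ... Unused.
#' @return One-row tibble: `Q`, `radius`, `flow_index`, `consistency_index`,
#'   `wall_shear_rate`, `wall_viscosity`, `centerline_velocity`.
#' @method glance nozzle_flow_profile
#' @export
glance.nozzle_flow_profile <- function(x, ...) {
  tibble::tibble(
    Q = attr(x, "Q"),
    radius = attr(x, "radius"),
    flow_index = attr(x, "flow_index"),
    consistency_index = attr(x, "consistency_index"),
    wall_shear_rate = attr(x, "wall_shear_rate"),
    wall_viscosity = attr(x, "wall_viscosity"),
    centerline_velocity = x$velocity[1]
  )
}

#' Plot nozzle flow profiles
#'
#' @param object A `nozzle_flow_profile`.
#' @param ... Unused.
#' @return A ggplot faceting velocity, shear rate (and apparent viscosity if
#'   present) against radial position.
#' @method autoplot nozzle_flow_profile
#' @export
autoplot.nozzle_flow_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"r",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r * 1e6, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Radial position (µm)", y = NULL,
                  title = sprintf("Nozzle flow profile (n = %.2f)",
                                  attr(object, "flow_index")))
}
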