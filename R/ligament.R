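# Ligament / droplet metrology: gravimetric calibration, velocity from
# stroboscopic displacement sweeps, geometric descriptors.

#' Solution density from a weighed known volume
#'
#' @param net_mass Net mass(es) of the pipetted aliquot, kg.
#' @param known_volume Pipetted volume, m³.
#' @return Tibble with `density` (mean over replicates, kg/m³), `sd` and `n`.
#' @export
density_from_mass <- function(net_mass, known_volume) {
  stopifnot(all(net_mass > 0), known_volume > 0)
  rho <- net_mass / known_volume
  tibble::tibble(
    density = mean(rho),
    sd = if (length(rho) > 1) stats::sd(rho) else 0,
    n = length(rho)
  )
}

#' Gravimetric per-drop volume calibration
#'
#' Each burst dispenses a fixed number of droplets into a pre-weighed tube;
#' the per-drop volume is mass / (drops × density). The session is accepted
#' only if the coefficient of variation over replicate bursts at the
#' operating dwell is at most `cv_max` AND the ordinary least-squares fit of
#' burst-mean volume versus dwell time over at least three distinct dwell
#' times reaches `r2_min`. Both thresholds are inclusive.
#'
#' @param data Data frame with columns `mass` (net burst mass, kg), `drops`
#'   (droplets per burst), `dwell` (valve dwell time, s).
#' @param density Solution density, kg/m³.
#' @param operating_dwell Dwell time (s) whose replicate bursts define the
#'   mean volume and CV; defaults to the most frequent dwell in `data`.
#' @param cv_max Acceptance bound on the coefficient of variation, percent.
#' @param r2_min Acceptance bound on the volume-vs-dwell linearity R².
#' @return One-row tibble: `per_drop_volume` (m³), `cv` (%), `linearity_r2`
#'   (NA if fewer than 3 distinct dwells), `n_bursts`, `accepted`.
#' @export
calibrate_drop_volume <- function(data, density,
                                  operating_dwell = NULL,
                                  cv_max = 5, r2_min = 0.99) {
  stopifnot(is.data.frame(data),
            all(c("mass", "drops", "dwell") %in% names(data)),
            density > 0)
  if (nrow(data) < 3) {
    stop("calibration needs at least 3 bursts (got ", nrow(data), ")",
         call. = FALSE)
  }
  stopifnot(all(data$mass > 0), all(data$drops >= 1), all(data$dwell > 0))
  vol <- data$mass / (data$drops * density)

  if (is.null(operating_dwell)) {
    operating_dwell <- as.numeric(names(sort(table(data$dwell),
                                             decreasing = TRUE))[1])
  }
  at_op <- abs(data$dwell - operating_dwell) < 1e-12
  v_op <- vol[at_op]
  if (length(v_op) < 3) {
    stop("fewer than 3 bursts at the operating dwell time", call. = FALSE)
  }
  v_mean <- mean(v_op)
  cv <- 100 * stats::sd(v_op) / v_mean

  dwells <- unique(data$dwell)
  if (length(dwells) >= 3) {
    means <- as.numeric(tapply(vol, data$dwell, mean))
    dw <- sort(dwells)
    fit <- stats::lm(means ~ dw)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((means - mean(means))^2)
    # an exactly linear (incl. constant) volume-dwell relation is a perfect
    # fit even when the total variance vanishes
    r2 <- if (ss_res <= (1e-9 * mean(means))^2) 1 else 1 - ss_res / ss_tot
  } else {
    r2 <- NA_real_
  }
  accepted <- !is.na(r2) && cv <= cv_max && r2 >= r2_min

  tibble::tibble(
    per_drop_volume = v_mean,
    cv = cv,
    linearity_r2 = r2,
    n_bursts = nrow(data),
    accepted = accepted
  )
}

#' Ligament velocity from a displacement sweep
#'
#' Fits leading-edge displacement against time and reports the slope as the
#' mean jet velocity. The default is the ordinary least-squares slope over
#' the full sweep; `method = "theil_sen"` uses the median of pairwise slopes,
#' robust to occasional mis-tracked frames.
#'
#' @param data Data frame with strictly increasing `time` (s) and `position`
#'   (m) columns, at least 3 rows.
#' @param method `"ols"` (default) or `"theil_sen"`.
#' @return One-row tibble: `velocity` (m/s), `se` (standard error; NA for
#'   Theil–Sen), `n_frames`, `method`.
#' @export
estimate_velocity <- function(data, method = c("ols", "theil_sen")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data),
            all(c("time", "position") %in% names(data)))
  t <- data$time; x <- data$position
  stopifnot(length(t) >= 3, length(t) == length(x), all(diff(t) > 0))
  if (diff(range(t)) == 0) stop("zero time span", call. = FALSE)

  if (method == "ols") {
    fit <- stats::lm(x ~ t)
    v <- unname(stats::coef(fit)[2])
    # suppress the "essentially perfect fit" note on jitter-free sweeps
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  } else {
    ij <- utils::combn(length(t), 2)
    v <- stats::median((x[ij[2, ]] - x[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]]))
    se <- NA_real_
  }
  tibble::tibble(velocity = v, se = se, n_frames = length(t),
                 method = method)
}

#' Ligament aspect ratio
#'
#' L_ar = L_l / D: ligament length normalised by the nozzle orifice diameter.
#'
#' @param length Ligament length, m (vectorised).
#' @param nozzle_diameter Nozzle orifice diameter, m.
#' @return Dimensionless aspect ratio(s).
#' @examples
#' aspect_ratio(0.336e-3, 0.250e-3) # 1.344
#' @export
aspect_ratio <- function(length, nozzle_diameter) {
  stopifnot(all(length > 0), all(nozzle_diameter > 0))
  length / nozzle_diameter
}

#' Volume-equivalent sphere diameter
#'
#' d_eq = (6V/π)^(1/3): the diameter of the sphere holding the measured
#' ligament/droplet volume, linking gravimetric volumes to imaged droplet
#' diameters.
#'
#' @param volume Volume(s), m³, > 0.
#' @return Equivalent diameter(s), m.
#' @export
equivalent_diameter <- function(volume) {
  stopifnot(all(volume > 0))
  (6 * volume / pi)^(1 / 3)
}

#' Assemble ligament metrics for one condition
#'
#' @param volume Gravimetric per-drop (ligament) volume, m³.
#' @param length Ligament length, m (optional).
#' @param velocity Jet velocity, m/s.
#' @param nozzle_diameter Nozzle orifice diameter, m.
#' @return One-row tibble: `volume`, `length`, `aspect_ratio`,
#'   `equivalent_diameter`, `velocity`.
#' @export
ligament_metrics <- function(volume, velocity, nozzle_diameter,
                             length = NA_real_) {
  stopifnot(volume > 0, velocity > 0, nozzle_diameter > 0)
  tibble::tibble(
    volume = volume,
    length = length,
    aspect_ratio = if (is.na(length)) NA_real_
                   else aspect_ratio(length, nozzle_diameter),
    equivalent_diameter = equivalent_diameter(volume),
    velocity = velocity
  )
}
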