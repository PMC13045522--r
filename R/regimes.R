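# Regime classification and printability-map construction.
#
# Canonical drop-on-demand band: 1 <= Z <= 10 printable (boundaries
# inclusive), Z > 10 satellite-prone, Z < 1 viscous/energy-limited.

#' Default actuation-frequency band table
#'
#' Piecewise recommendation of the usable jetting-frequency band by Z,
#' encoding practitioner guidance for a 250 µm microvalve nozzle: very
#' viscous inks (Z < 1) need slow actuation so each ligament can pinch off;
#' the printable band supports mid-range frequencies; moderately high-Z
#' fluids eject cleanly at the top of the window; extremely low-viscosity
#' inks are throttled back to suppress satellites. Bands are clipped to the
#' valve's global operating window. The table is data, not code — pass an
#' edited copy to [recommend_frequency()] to re-derive bands from your own
#' observations.
#'
#' @return Tibble with columns `z_min`, `z_max` (band applies to
#'   `z_min <= Z < z_max`, last row inclusive), `f_low`, `f_high` (Hz).
#' @export
default_frequency_bands <- function() {
  tibble::tibble(
    z_min = c(0, 1, 5, 30),
    z_max = c(1, 5, 30, Inf),
    f_low = c(20, 50, 100, 20),
    f_high = c(50, 150, 200, 100)
  )
}

#' Classify the Z number into jetting regimes
#'
#' @param z Positive Z = 1/Oh value(s).
#' @return Factor with levels `viscous_limited` (Z < 1), `printable`
#'   (1 ⩽ Z ⩽ 10, boundaries inclusive), `satellite_prone` (Z > 10).
#' @export
classify_z <- function(z) {
  stopifnot(all(z > 0, na.rm = TRUE))
  out <- ifelse(z < 1, "viscous_limited",
                ifelse(z <= 10, "printable", "satellite_prone"))
  factor(out, levels = c("viscous_limited", "printable", "satellite_prone"))
}

#' Classify droplet impact by splash parameter
#'
#' Splash requires K_splash strictly above the threshold; the boundary value
#' classifies as deposition. The default threshold 57.7 is the classical
#' deposition/splash limit from the droplet-impact literature, not a value
#' measured in this workflow, and should be overridden when a
#' substrate-specific threshold is known.
#'
#' @param k_splash Positive splash parameter(s), Oh·Re^1.25.
#' @param threshold Critical value K_c (> 0).
#' @return Factor with levels `deposition`, `splash`.
#' @export
classify_splash <- function(k_splash, threshold = 57.7) {
  stopifnot(all(k_splash > 0, na.rm = TRUE), threshold > 0)
  factor(ifelse(k_splash > threshold, "splash", "deposition"),
         levels = c("deposition", "splash"))
}

#' Recommend an actuation-frequency band
#'
#' Looks each Z up in a frequency-band table (see
#' [default_frequency_bands()]) and clips the result to the global operating
#' window.
#'
#' @param z Positive Z value(s).
#' @param bands Band table; see [default_frequency_bands()].
#' @param operating_window Two-element numeric, the valve's usable frequency
#'   window in Hz; all bands are clipped into it.
#' @return Tibble with columns `z`, `f_low`, `f_high` (Hz).
#' @export
recommend_frequency <- function(z, bands = default_frequency_bands(),
                                operating_window = c(20, 200)) {
  stopifnot(all(z > 0, na.rm = TRUE), is.data.frame(bands),
            all(c("z_min", "z_max", "f_low", "f_high") %in% names(bands)),
            length(operating_window) == 2,
            operating_window[1] < operating_window[2])
  idx <- vapply(z, function(zi) {
    if (is.na(zi)) return(NA_integer_)
    hit <- which(zi >= bands$z_min &
                   (zi < bands$z_max | (is.infinite(bands$z_max) &
                                          zi >= bands$z_min)))
    hit[length(hit)]
  }, integer(1))
  tibble::tibble(
    z = z,
    f_low = pmax(bands$f_low[idx], operating_window[1]),
    f_high = pmin(bands$f_high[idx], operating_window[2])
  )
}

#' Full regime label for a set of jetting conditions
#'
#' Combines the Z-band class, the splash class, and the frequency-band
#' recommendation with a text trace of the thresholds applied.
#'
#' @param data Data frame with columns `z` and `k_splash` (e.g. the output
#'   of [dimensionless_numbers()] or [read_dimensionless_table()]).
#' @param splash_threshold Critical splash parameter; see
#'   [classify_splash()].
#' @param bands Frequency-band table; see [default_frequency_bands()].
#' @return `data` with `z_class`, `splash_class`, `f_low`, `f_high` and
#'   `rationale` columns appended.
#' @export
classify_regimes <- function(data, splash_threshold = 57.7,
                             bands = default_frequency_bands()) {
  stopifnot(is.data.frame(data), all(c("z", "k_splash") %in% names(data)))
  freq <- recommend_frequency(data$z, bands = bands)
  dplyr::mutate(
    tibble::as_tibble(data),
    z_class = classify_z(.data$z),
    splash_class = classify_splash(.data$k_splash, splash_threshold),
    f_low = freq$f_low,
    f_high = freq$f_high,
    rationale = sprintf(
      "Z=%.3g in [1,10]? -> %s; K_splash=%.3g vs K_c=%.3g -> %s; band %g-%g Hz",
      .data$z, .data$z_class, .data$k_splash, splash_threshold,
      .data$splash_class, .data$f_low, .data$f_high)
  )
}

.map_axes <- list(
  Lar_Oh = c("l_ar", "oh"),
  We_Fr  = c("we", "fr"),
  We_Oh  = c("we", "oh"),
  We_Re  = c("we", "re"),
  Oh_Re  = c("oh", "re"),
  Oh_f   = c("oh", "f")
)

#' Build a printability-map dataset
#'
#' Places each classified condition in one of the six map planes —
#' aspect-ratio–Oh, We–Fr, We–Oh, We–Re, Oh–Re, or Oh–frequency — together
#' with the regime-boundary loci expressed in that plane's coordinates.
#' Records missing a required coordinate are skipped and counted. In We–Re
#' space the Z = const loci are the curves Re = √We / Oh = √We · Z; in Oh–Re
#' and We–Oh space they are vertical/horizontal lines at Oh = 1/Z; on the
#' Oh–f plane the operating window's 20 and 200 Hz edges are drawn.
#'
#' @param records Classified condition table (see [classify_regimes()]); the
#'   `Oh_f` map additionally needs an `f` column (actuation frequency, Hz)
#'   and `Lar_Oh` an `l_ar` column.
#' @param map_type One of `"Lar_Oh"`, `"We_Fr"`, `"We_Oh"`, `"We_Re"`,
#'   `"Oh_Re"`, `"Oh_f"`.
#' @param z_boundaries Z values whose loci delimit the printable band.
#' @param operating_window Frequency window drawn on the `Oh_f` map, Hz.
#' @return A list of class `"printability_map"` with elements `map_type`,
#'   `points` (tibble with `x`, `y` and all record columns), `boundaries`
#'   (tibble of named curves: `boundary`, `x`, `y`), `n_skipped`.
#' @export
build_map <- function(records, map_type = names(.map_axes),
                      z_boundaries = c(1, 10),
                      operating_window = c(20, 200)) {
  map_type <- match.arg(map_type)
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  ax <- .map_axes[[map_type]]
  missing_ax <- setdiff(ax, names(records))
  if (length(missing_ax) == length(ax)) {
    stop("records lack the coordinates (", paste(ax, collapse = ", "),
         ") required for map '", map_type, "'", call. = FALSE)
  }
  if (length(missing_ax) > 0) {
    stop("records lack required coordinate '", missing_ax[1], "' for map '",
         map_type, "'", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  ok <- is.finite(records[[ax[1]]]) & is.finite(records[[ax[2]]])
  n_skipped <- sum(!ok)
  pts <- records[ok, , drop = FALSE]
  pts$x <- pts[[ax[1]]]
  pts$y <- pts[[ax[2]]]

  boundaries <- switch(
    map_type,
    We_Re = {
      we_grid <- 10^seq(-2, 3, length.out = 100)
      purrr::map_dfr(z_boundaries, function(zb) {
        tibble::tibble(boundary = sprintf("Z = %g", zb),
                       x = we_grid, y = sqrt(we_grid) * zb)
      })
    },
    Oh_Re = ,
    We_Oh = ,
    Lar_Oh = {
      # Z loci are Oh = 1/Z lines perpendicular to the Oh axis
      purrr::map_dfr(z_boundaries, function(zb) {
        tibble::tibble(boundary = sprintf("Z = %g", zb),
                       x = if (map_type == "Lar_Oh" || map_type == "We_Oh")
                         NA_real_ else 1 / zb,
                       y = if (map_type == "Lar_Oh" || map_type == "We_Oh")
                         1 / zb else NA_real_)
      })
    },
    Oh_f = tibble::tibble(
      boundary = sprintf("f = %g Hz", operating_window),
      x = NA_real_, y = operating_window
    ),
    We_Fr = tibble::tibble(boundary = character(), x = numeric(),
                           y = numeric())
  )

  structure(
    list(map_type = map_type, points = pts, boundaries = boundaries,
         n_skipped = n_skipped),
    class = "printability_map"
  )
}

#' @export
print.printability_map <- function(x, ...) {
  cat("Printability map <", x$map_type, ">: ", nrow(x$points), " points",
      if (x$n_skipped > 0) paste0(" (", x$n_skipped, " skipped)"), "\n",
      sep = "")
  invisible(x)
}

#' Plot a printability map
#'
#' @param object A `printability_map` from [build_map()].
#' @param ... Unused.
#' @return A ggplot: conditions coloured by regime class with the Z-band /
#'   frequency boundary loci overlaid; log axes where the plane spans more
#'   than two decades.
#' @method autoplot printability_map
#' @export
autoplot.printability_map <- function(object, ...) {
  ax <- .map_axes[[object$map_type]]
  pts <- object$points
  colour_var <- if ("z_class" %in% names(pts)) "z_class" else NULL
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    (if (!is.null(colour_var))
      ggplot2::geom_point(ggplot2::aes(colour = .data$z_class,
                                       shape = factor(.data$t20 > 0)),
                          size = 2.5)
     else ggplot2::geom_point(size = 2.5)) +
    ggplot2::labs(x = toupper(ax[1]), y = toupper(ax[2]),
                  colour = "Regime", shape = "T20",
                  title = paste("Printability map:", object$map_type))
  b <- object$boundaries
  if (nrow(b) > 0) {
    if (all(is.na(b$x))) {
      p <- p + ggplot2::geom_hline(yintercept = unique(b$y),
                                   linetype = "dashed", colour = "grey40")
    } else if (all(is.na(b$y))) {
      p <- p + ggplot2::geom_vline(xintercept = unique(b$x),
                                   linetype = "dashed", colour = "grey40")
    } else {
      p <- p + ggplot2::geom_line(
        data = b, ggplot2::aes(group = .data$boundary),
        linetype = "dashed", colour = "grey40")
    }
  }
  span_decades <- function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(0)
    log10(max(v) / min(v))
  }
  if (span_decades(pts$x) > 2) p <- p + ggplot2::scale_x_log10()
  if (span_decades(pts$y) > 2) p <- p + ggplot2::scale_y_log10()
  p
}
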