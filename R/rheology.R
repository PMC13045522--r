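# Flow-curve ingestion and the power-law viscosity fit.
#
# Model: mu = K * gamma_dot^(n - 1).  The fit minimises
#   sum_i w_i * (mu_i - K g_i^(n-1))^2,   w_i = 1/mu_i^2 (inverse_square) or 1,
# with damped (Levenberg-Marquardt) least squares started from a log-log
# ordinary regression.  Inverse-square weighting makes the objective the sum
# of squared *relative* residuals, which keeps the low-shear decades from
# being swamped by the high-viscosity points.

#' Read a rheometer flow curve
#'
#' Loads a delimited flow-curve table, drops unusable rows (shear rate at or
#' below the floor, non-finite or non-positive viscosity) and returns the
#' cleaned curve sorted by shear rate. Rotational rheometer sweeps commonly
#' start at a nominal 0 1/s; such rows carry no viscosity information and are
#' removed and counted.
#'
#' @param path Path to a CSV file with a header row.
#' @param shear_col,visc_col Column names holding shear rate (1/s) and
#'   apparent viscosity (Pa·s). Defaults match the package's CSV dialect.
#' @param shear_floor Rows with shear rate ⩽ this value (1/s) are dropped.
#' @param temperature,direction,formulation Optional metadata attached as
#'   columns (`direction` is `"up"` or `"down"`; `formulation` a one-row
#'   tibble from [formulation()]).
#' @return A tibble with columns `shear_rate`, `viscosity` plus metadata,
#'   with attributes `n_dropped` (rows removed) and class `"flow_curve"`.
#' @export
read_flow_curve <- function(path,
                            shear_col = "shear_rate_1_per_s",
                            visc_col = "viscosity_Pa_s",
                            shear_floor = 1e-3,
                            temperature = NA_real_,
                            direction = "up",
                            formulation = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  flow_curve(tab, shear_col = shear_col, visc_col = visc_col,
             shear_floor = shear_floor, temperature = temperature,
             direction = direction, formulation = formulation)
}

#' Validate and clean an in-memory flow-curve table
#'
#' @param data A data frame holding the raw sweep.
#' @inheritParams read_flow_curve
#' @return A cleaned `flow_curve` tibble; see [read_flow_curve()].
#' @export
flow_curve <- function(data,
                       shear_col = "shear_rate_1_per_s",
                       visc_col = "viscosity_Pa_s",
                       shear_floor = 1e-3,
                       temperature = NA_real_,
                       direction = "up",
                       formulation = NULL) {
  stopifnot(is.data.frame(data), shear_floor > 0)
  direction <- match.arg(direction, c("up", "down"))
  for (col in c(shear_col, visc_col)) {
    if (!col %in% names(data)) {
      stop("flow-curve table is missing column '", col, "'", call. = FALSE)
    }
  }
  g <- as.numeric(data[[shear_col]])
  mu <- as.numeric(data[[visc_col]])
  keep <- is.finite(g) & is.finite(mu) & g > shear_floor & mu > 0
  n_dropped <- sum(!keep)
  g <- g[keep]; mu <- mu[keep]
  if (length(g) < 5) {
    stop("flow curve has fewer than 5 usable points after cleaning (",
         length(g), " kept, ", n_dropped, " dropped)", call. = FALSE)
  }
  ord <- order(g)
  out <- tibble::tibble(
    shear_rate = g[ord],
    viscosity = mu[ord],
    temperature = temperature,
    direction = direction
  )
  if (!is.null(formulation)) {
    out <- dplyr::bind_cols(out, formulation[rep(1, nrow(out)), ])
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("flow_curve", class(out))
  out
}

#' Fit the power-law viscosity model to a flow curve
#'
#' Fits \eqn{\mu = K \dot\gamma^{n-1}} by damped (Levenberg–Marquardt)
#' nonlinear least squares. With `weighting = "inverse_square"` the residuals
#' are weighted by \eqn{w_i = 1/\mu_i^2}, i.e. relative residuals are
#' minimised; `"none"` gives ordinary least squares in linear viscosity
#' space. The starting point is the ordinary log–log regression of viscosity
#' on shear rate, which is near-global for power-law data. Parameters are
#' bounded to K ∈ (1e-8, 1e4) Pa·sⁿ and n ∈ (0.05, 1.5); a fit pinned at a
#' bound is flagged.
#'
#' @param data A `flow_curve` tibble or any data frame with `shear_rate`
#'   (1/s) and `viscosity` (Pa·s) columns.
#' @param weighting `"inverse_square"` (default) or `"none"`.
#' @param max_iter Maximum solver iterations.
#' @return An object of class `"power_law_fit"`: a list with
#'   `consistency_index` (K, Pa·sⁿ), `flow_index` (n), `weighting`, `rss`
#'   (weighted residual sum of squares), `n_points`, `converged`,
#'   `at_bounds`, and `data` (the fitted points with fitted values and
#'   residuals). Use [tidy.power_law_fit()] / [glance.power_law_fit()] for
#'   tabular summaries.
#' @examples
#' fc <- gen_flow_curve(K = 2, n = 0.5, seed = 1, noise = "none")
#' fit <- fit_power_law(fc)
#' glance(fit)
#' @export
fit_power_law <- function(data, weighting = c("inverse_square", "none"),
                          max_iter = 200) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(data),
            all(c("shear_rate", "viscosity") %in% names(data)))
  g <- data$shear_rate
  mu <- data$viscosity
  stopifnot(length(g) >= 5, all(g > 0), all(mu > 0))

  w <- if (weighting == "inverse_square") 1 / mu^2 else rep(1, length(mu))
  sw <- sqrt(w)

  # log-log OLS start: log mu = log K + (n - 1) log g
  ols <- stats::lm(log(mu) ~ log(g))
  start <- c(logK = unname(stats::coef(ols)[1]),
             n = unname(stats::coef(ols)[2]) + 1)

  lower <- c(log(1e-8), 0.05)
  upper <- c(log(1e4), 1.5)
  start[1] <- min(max(start[1], lower[1]), upper[1])
  start[2] <- min(max(start[2], lower[2]), upper[2])

  resid_fn <- function(p) sw * (mu - exp(p[1]) * g^(p[2] - 1))
  nlm <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-14, ptol = 1e-14)
  )
  K <- exp(nlm$par[[1]])
  n <- nlm$par[[2]]
  converged <- nlm$info %in% 1:4
  at_bounds <- any(abs(nlm$par - lower) < 1e-10) ||
    any(abs(nlm$par - upper) < 1e-10)

  fitted <- K * g^(n - 1)
  structure(
    list(
      consistency_index = K,
      flow_index = n,
      weighting = weighting,
      rss = sum(w * (mu - fitted)^2),
      n_points = length(g),
      converged = converged,
      at_bounds = at_bounds,
      data = tibble::tibble(shear_rate = g, viscosity = mu,
                            fitted = fitted, residual = mu - fitted)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law viscosity fit: mu = K * shear_rate^(n-1)\n")
  cat(sprintf("  K = %.6g Pa.s^n   n = %.4f   (%s weighting, %d points)\n",
              x$consistency_index, x$flow_index, x$weighting, x$n_points))
  cat(sprintf("  weighted RSS = %.4g   converged = %s%s\n", x$rss,
              x$converged, if (x$at_bounds) "   [at parameter bound]" else ""))
  invisible(x)
}

#' Tidy a power-law fit
#' @param x A `power_law_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("consistency_index", "flow_index"),
    estimate = c(x$consistency_index, x$flow_index)
  )
}

#' One-row summary of a power-law fit
#' @inheritParams tidy.power_law_fit
#' @return One-row tibble with K, n, weighting, rss, n_points, converged.
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    consistency_index = x$consistency_index,
    flow_index = x$flow_index,
    weighting = x$weighting,
    rss = x$rss,
    n_points = x$n_points,
    converged = x$converged,
    at_bounds = x$at_bounds
  )
}

#' Apparent viscosity from a power-law fit
#'
#' Evaluates \eqn{\mu = K \max(\dot\gamma, \dot\gamma_{floor})^{n-1}}. The
#' shear-rate floor regularises the zero-shear singularity of shear-thinning
#' fits (n < 1), giving a high but finite viscosity at vanishing shear rate.
#'
#' @param fit A `power_law_fit`, or a list with `consistency_index` and
#'   `flow_index`.
#' @param shear_rate Shear rate(s), 1/s, ⩾ 0.
#' @param floor Regularisation floor, 1/s (> 0).
#' @return Apparent viscosity in Pa·s, same length as `shear_rate`.
#' @export
apparent_viscosity <- function(fit, shear_rate, floor = 1e-2) {
  stopifnot(all(shear_rate >= 0), floor > 0)
  K <- fit$consistency_index
  n <- fit$flow_index
  K * pmax(shear_rate, floor)^(n - 1)
}

#' Summarise oscillatory moduli over the linear viscoelastic region
#'
#' Averages the storage and loss moduli over the low-strain window where both
#' are strain-independent, and reports the loss tangent tan δ = G″/G′ from
#' the ratio of the window means.
#'
#' @param data Data frame with columns `strain` (dimensionless amplitude),
#'   `storage_modulus` and `loss_modulus` (Pa).
#' @param lve_strain_max Upper strain bound of the linear viscoelastic window.
#' @return One-row tibble: `g_prime`, `g_double_prime` (Pa), `tan_delta`,
#'   `n_points`.
#' @export
summarize_moduli <- function(data, lve_strain_max) {
  stopifnot(is.data.frame(data),
            all(c("strain", "storage_modulus", "loss_modulus") %in%
                  names(data)),
            lve_strain_max > 0)
  win <- dplyr::filter(data, .data$strain <= lve_strain_max)
  if (nrow(win) < 3) {
    stop("fewer than 3 points with strain <= ", lve_strain_max,
         " in the linear viscoelastic window", call. = FALSE)
  }
  gp <- mean(win$storage_modulus)
  gpp <- mean(win$loss_modulus)
  tibble::tibble(
    g_prime = gp,
    g_double_prime = gpp,
    tan_delta = gpp / gp,
    n_points = nrow(win)
  )
}

#' Plot a power-law fit against its flow curve
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot with log-log axes: measured points and the fitted curve.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$shear_rate, y = .data$viscosity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Shear rate (1/s)", y = "Apparent viscosity (Pa·s)",
      title = sprintf("Power-law fit: K = %.3g Pa·sⁿ, n = %.3f",
                      object$consistency_index, object$flow_index)
    )
}
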