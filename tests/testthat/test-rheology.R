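test_that("flow-curve loading cleans and validates", {
  g29 <- 10^seq(-1, 3, length.out = 29)
  tab <- tibble::tibble(
    shear_rate_1_per_s = c(0, g29),
    viscosity_Pa_s = c(5, 2 * g29^(-0.5))
  )
  fc <- flow_curve(tab)
  expect_equal(nrow(fc), 29)
  expect_equal(attr(fc, "n_dropped"), 1) # the gamma-dot = 0 row
  expect_true(all(diff(fc$shear_rate) > 0))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  expect_equal(nrow(read_flow_curve(path)), 29)

  expect_error(flow_curve(tab[, 1, drop = FALSE]), "viscosity_Pa_s")
  expect_error(flow_curve(tab[1:4, ]), "fewer than 5")
})

test_that("noiseless power-law data is recovered to 1e-6 for a range of n", {
  for (n_true in c(0.2, 0.5, 0.8, 1.0)) {
    fc <- gen_flow_curve(K = 2, n = n_true, n_points = 20, noise = "none")
    fit <- fit_power_law(fc)
    expect_true(fit$converged)
    expect_equal(fit$consistency_index, 2, tolerance = 1e-6)
    expect_equal(fit$flow_index, n_true, tolerance = 1e-6)
  }
})

test_that("a Newtonian fluid fits with n = 1 and K = mu", {
  fc <- gen_flow_curve(K = 0.005, n = 1, noise = "none")
  fit <- fit_power_law(fc)
  expect_equal(fit$flow_index, 1, tolerance = 1e-9)
  expect_equal(fit$consistency_index, 0.005, tolerance = 1e-9)
})

test_that("inverse-square weighted fit matches the grid-search oracle on
           heteroscedastic data", {
  fc <- gen_flow_curve(K = 0.8, n = 0.45, seed = 42, n_points = 30,
                       noise = "multiplicative_lognormal",
                       noise_level = 0.10)
  fit <- fit_power_law(fc, weighting = "inverse_square")
  oracle <- grid_fit_power_law(fc$shear_rate, fc$viscosity)
  # agreement within one grid step per parameter
  expect_lt(abs(fit$flow_index - unname(oracle["n"])),
            diff(c(0.1, 1.4)) / 199)
  expect_lt(abs(log(fit$consistency_index) - log(unname(oracle["K"]))),
            diff(log(c(1e-4, 1e2))) / 199)
  # and the LM objective is no worse than the oracle's best grid point
  w <- 1 / fc$viscosity^2
  obj <- function(K, n) sum(w * (fc$viscosity - K * fc$shear_rate^(n - 1))^2)
  expect_lte(obj(fit$consistency_index, fit$flow_index),
             unname(oracle["obj"]) * (1 + 1e-9))
})

test_that("stochastic recovery: median relative error under 2% at 1% noise", {
  errs <- vapply(1:200, function(s) {
    fc <- gen_flow_curve(K = 0.05, n = 0.6, seed = s, n_points = 30,
                         noise = "multiplicative_lognormal",
                         noise_level = 0.01)
    fit <- fit_power_law(fc)
    c(abs(fit$consistency_index - 0.05) / 0.05,
      abs(fit$flow_index - 0.6) / 0.6)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.02)
  expect_lt(median(errs[2, ]), 0.02)
})

test_that("inverse-square weighting equals minimising relative residuals", {
  fc <- gen_flow_curve(K = 1.5, n = 0.35, noise = "none")
  fit <- fit_power_law(fc, weighting = "inverse_square")
  rel_resid <- (fc$viscosity - fit$consistency_index *
                  fc$shear_rate^(fit$flow_index - 1)) / fc$viscosity
  expect_equal(fit$rss, sum(rel_resid^2), tolerance = 1e-12)
})

test_that("apparent viscosity honours the shear-rate floor and monotonicity", {
  fit <- list(consistency_index = 2, flow_index = 0.5)
  expect_equal(apparent_viscosity(fit, 4), 1.0)
  expect_equal(apparent_viscosity(fit, 0, floor = 1e-2), 2 * (1e-2)^(-0.5))
  newt <- list(consistency_index = 0.005, flow_index = 1)
  expect_equal(apparent_viscosity(newt, 0), 0.005)

  g <- 10^seq(-3, 3, length.out = 50)
  expect_true(all(diff(apparent_viscosity(fit, g)) <= 0))
  expect_true(all(diff(apparent_viscosity(newt, g)) == 0))
})

test_that("moduli summary averages the linear viscoelastic window", {
  sweep <- tibble::tibble(strain = 10^seq(-3, 0, length.out = 20),
                          storage_modulus = 10, loss_modulus = 5)
  s <- summarize_moduli(sweep, lve_strain_max = 0.1)
  expect_equal(s$g_prime, 10)
  expect_equal(s$tan_delta, 0.5)

  # plateau-then-decay: window restricted to the plateau recovers it exactly
  decay <- dplyr::mutate(
    sweep,
    storage_modulus = ifelse(strain > 0.01, 10 * (0.01 / strain), 10),
    loss_modulus = ifelse(strain > 0.01, 10 * (0.01 / strain), 10))
  p <- summarize_moduli(decay, lve_strain_max = 0.01)
  expect_equal(p$g_prime, 10, tolerance = 1e-9)
  expect_equal(p$tan_delta, 1, tolerance = 1e-9)

  expect_error(summarize_moduli(sweep, lve_strain_max = 1e-5), "fewer than 3")
})

test_that("fit accessors return tidy tibbles", {
  fit <- fit_power_law(gen_flow_curve(K = 2, n = 0.5, noise = "none"))
  td <- tidy(fit)
  expect_equal(td$term, c("consistency_index", "flow_index"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
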