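test_that("dimensionless numbers satisfy their defining scaling laws", {
  base <- tibble::tibble(density = 1000, surface_tension = 0.0539,
                         viscosity = 1e-3, velocity = 4.77,
                         diameter = 2.5e-4)
  d0 <- dimensionless_numbers(base)
  expect_equal(d0$oh, sqrt(d0$we) / d0$re, tolerance = 1e-12)
  expect_equal(d0$z * d0$oh, 1, tolerance = 1e-12)
  expect_equal(d0$bond, d0$we / d0$fr^2, tolerance = 1e-12)

  d2v <- dimensionless_numbers(dplyr::mutate(base, velocity = velocity * 2))
  expect_equal(d2v$we / d0$we, 4)
  expect_equal(d2v$re / d0$re, 2)
  expect_equal(d2v$fr / d0$fr, 2)
  expect_equal(d2v$oh, d0$oh)

  d2mu <- dimensionless_numbers(dplyr::mutate(base, viscosity = viscosity * 2))
  expect_equal(d2mu$re / d0$re, 0.5)
  expect_equal(d2mu$oh / d0$oh, 2)
  expect_equal(d2mu$z / d0$z, 0.5)
  expect_equal(d2mu$we, d0$we)
  expect_equal(d2mu$fr, d0$fr)
})

test_that("viscosity can be derived from a power-law fit at v/D", {
  fit <- structure(list(consistency_index = 2, flow_index = 0.5),
                   class = "power_law_fit")
  cond <- tibble::tibble(density = 1000, surface_tension = 0.05,
                         velocity = 4, diameter = 2.5e-4)
  d <- dimensionless_numbers(cond, fit = fit)
  expect_equal(d$viscosity, 2 * (4 / 2.5e-4)^(-0.5))
  expect_equal(attr(d, "viscosity_source"), "power_law_at_char_shear")
  expect_error(dimensionless_numbers(cond), "viscosity")
})

test_that("Oh = sqrt(We)/Re reproduces every printed per-condition value
           within 1%", {
  tab <- printed_conditions()
  full <- tab[stats::complete.cases(tab[, c("we", "re", "oh")]), ]
  expect_gte(nrow(full), 9)
  oh <- oh_from_we_re(full$we, full$re)
  expect_true(all(abs(oh - full$oh) / full$oh < 0.01))
})

test_that("splash parameter matches the printed approximate values", {
  # (~60, ~52) fibrinogen; (~15, ~0.6) collagen; (~41, ~6) Matrigel;
  # (~44, ~11) alginate -- 5% for exact-Oh rows, 10% for tilde values
  cases <- list(
    list(oh = oh_from_we_re(105.39, 1191.5), re = 1191.5, k = 60),
    list(oh = oh_from_we_re(95.97, 773.0), re = 773.0, k = 52),
    list(oh = 0.051, re = 95.011, k = 15),
    list(oh = 5.806, re = 0.163, k = 0.6),
    list(oh = oh_from_we_re(65.573, 637.390), re = 637.390, k = 41),
    list(oh = 0.2057, re = 14.836, k = 6),
    list(oh = oh_from_we_re(65.708, 871.11), re = 871.11, k = 44),
    list(oh = 0.0702, re = 57.812, k = 11)
  )
  for (cs in cases) {
    expect_equal(splash_parameter(cs$oh, cs$re), cs$k, tolerance = 0.10)
  }
  expect_equal(splash_parameter(1, 1), 1)
})

test_that("splash parameter and Z are monotone in their arguments", {
  oh <- 10^seq(-3, 1, length.out = 20)
  expect_true(all(diff(splash_parameter(oh, 100)) > 0))
  re <- 10^seq(-1, 3, length.out = 20)
  expect_true(all(diff(splash_parameter(0.1, re)) > 0))
  mu <- 10^seq(-4, 0, length.out = 20)
  z <- 1 / (mu / sqrt(1000 * 0.05 * 2.5e-4))
  expect_true(all(diff(z) < 0))
})

test_that("inversion recovers physical properties and round-trips", {
  inv <- invert_dimensionless(105.39, 1191.5, 96.278,
                              density = 1000, diameter = 2.5e-4)
  expect_equal(inv$velocity, 4.77, tolerance = 0.01)
  expect_equal(inv$surface_tension, 0.054, tolerance = 0.02)
  expect_equal(inv$viscosity, 1.0e-3, tolerance = 0.01)

  # Bond-number plausibility: recovered sigma in [0.03, 0.08] N/m for
  # densities across the aqueous range
  for (rho in c(990, 1050)) {
    s <- invert_dimensionless(105.39, 1191.5, 96.278, rho,
                              2.5e-4)$surface_tension
    expect_gt(s, 0.03); expect_lt(s, 0.08)
  }

  # property: forward after inverse is the identity, 1000 random draws
  withr::with_seed(7, {
    we <- 10^runif(1000, -1, 2.5)
    re <- 10^runif(1000, -1, 3.5)
    fr <- 10^runif(1000, 0.5, 2)
    rho <- runif(1000, 950, 1100)
    D <- runif(1000, 1e-4, 5e-4)
    inv <- invert_dimensionless(we, re, fr, rho, D)
    fwd <- dimensionless_numbers(
      tibble::tibble(density = rho, surface_tension = inv$surface_tension,
                     viscosity = inv$viscosity, velocity = inv$velocity,
                     diameter = D))
    expect_equal(fwd$we, we, tolerance = 1e-9)
    expect_equal(fwd$re, re, tolerance = 1e-9)
    expect_equal(fwd$fr, fr, tolerance = 1e-9)
  })
})

test_that("capillary and pinch-off time scales behave as stated", {
  tc <- capillary_time(1000, 0.07, 1.25e-4)
  expect_equal(tc, sqrt(1000 * (1.25e-4)^3 / 0.07), tolerance = 1e-12)
  expect_equal(tc, 1.67e-4, tolerance = 0.01)
  # quartering sigma doubles tau_c; radius -> 0 limit
  expect_equal(capillary_time(1000, 0.07 / 4, 1.25e-4) / tc, 2)
  expect_equal(capillary_time(1000, 0.07, 0), 0)

  p <- pinch_off_time(tc, oh = 0.01, alpha = 2)
  expect_equal(p$pinch_off_time, tc * 1.02)
  expect_equal(p$max_frequency, 1 / (tc * 1.02))
  expect_gte(p$pinch_off_time, p$capillary_time)
  # inviscid limit and degenerate coefficient
  expect_equal(pinch_off_time(tc, oh = 0)$pinch_off_time, tc)
  expect_equal(pinch_off_time(tc, oh = 5, alpha = 0)$max_frequency, 1 / tc)
})
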