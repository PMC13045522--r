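test_that("Z classification matches the canonical bands with closed
           boundaries", {
  expect_equal(as.character(classify_z(1 / 0.0086)), "satellite_prone")
  expect_equal(as.character(classify_z(1.6)), "printable")
  expect_equal(as.character(classify_z(1 / 5.806)), "viscous_limited")
  # boundary membership: Z = 1 and Z = 10 are printable
  expect_equal(as.character(classify_z(c(1, 10))),
               c("printable", "printable"))
  expect_equal(as.character(classify_z(0.999999)), "viscous_limited")
  expect_equal(as.character(classify_z(10.000001)), "satellite_prone")
})

test_that("splash classification uses a strict threshold", {
  expect_equal(as.character(classify_splash(60.3)), "splash")
  expect_equal(as.character(classify_splash(0.6)), "deposition")
  expect_equal(as.character(classify_splash(57.7)), "deposition") # boundary
  expect_equal(as.character(classify_splash(60.3, threshold = 100)),
               "deposition")
})

test_that("frequency recommendation follows the band table and stays in the
           operating window", {
  expect_equal(unlist(recommend_frequency(20)[, c("f_low", "f_high")]),
               c(f_low = 100, f_high = 200)) # moderately high Z
  expect_equal(unlist(recommend_frequency(1.6)[, c("f_low", "f_high")]),
               c(f_low = 50, f_high = 150)) # printable mid-band
  expect_equal(unlist(recommend_frequency(0.5)[, c("f_low", "f_high")]),
               c(f_low = 20, f_high = 50)) # viscous-limited
  expect_equal(unlist(recommend_frequency(116)[, c("f_low", "f_high")]),
               c(f_low = 20, f_high = 100)) # very low viscosity: throttle

  zs <- 10^seq(-1, 3, length.out = 200)
  bands <- recommend_frequency(zs)
  expect_true(all(bands$f_low >= 20 & bands$f_high <= 200))
  expect_true(all(bands$f_low < bands$f_high))
  # lower Z never yields a higher upper edge than the printable mid-band
  mid_upper <- recommend_frequency(3)$f_high
  expect_true(all(bands$f_high[zs < 1] <= mid_upper))
})

test_that("classify_regimes appends consistent labels and a rationale", {
  tab <- printed_conditions()
  tab <- tab[!is.na(tab$z) & !is.na(tab$k_splash), ]
  lab <- classify_regimes(tab)
  expect_equal(as.character(lab$z_class), as.character(classify_z(lab$z)))
  expect_equal(as.character(lab$splash_class),
               as.character(classify_splash(lab$k_splash)))
  expect_true(all(grepl("K_c=57.7", lab$rationale)))
})

test_that("printability maps place points and boundaries consistently", {
  tab <- classify_regimes(printed_conditions())
  full <- tab[!is.na(tab$we) & !is.na(tab$re), ]
  m <- build_map(full, "We_Re")
  expect_s3_class(m, "printability_map")
  expect_equal(nrow(m$points), nrow(full))

  # the Z = const loci satisfy Re = sqrt(We) * Z exactly
  b1 <- m$boundaries[m$boundaries$boundary == "Z = 1", ]
  expect_equal(b1$y, sqrt(b1$x) * 1, tolerance = 1e-12)
  b10 <- m$boundaries[m$boundaries$boundary == "Z = 10", ]
  expect_equal(b10$y, sqrt(b10$x) * 10, tolerance = 1e-12)
  # a point generated on the Z = 10 locus classifies printable
  expect_equal(as.character(classify_z(b10$y[1] / sqrt(b10$x[1]))),
               "printable")

  # fibrinogen lies above the Z = 10 locus (satellite side); collagen 7
  # below the Z = 1 locus
  fib <- m$points[m$points$bioink == "fibrinogen" & m$points$t20 == 0 &
                    m$points$concentration == 5, ]
  expect_gt(fib$re, sqrt(fib$we) * 10)
  col7 <- m$points[m$points$bioink == "collagen_I" & m$points$t20 == 0 &
                     m$points$concentration == 7, ]
  expect_lt(col7$re, sqrt(col7$we) * 1)

  # single mid-band record falls between the loci
  one <- classify_regimes(tibble::tibble(
    bioink = "other", t20 = 0, we = 25, re = sqrt(25) * 5, oh = 1 / 5,
    z = 5, k_splash = splash_parameter(1 / 5, sqrt(25) * 5)))
  m1 <- build_map(one, "Oh_Re")
  expect_gt(m1$points$x, 1 / 10) # between the Oh = 1/10 and Oh = 1 lines
  expect_lt(m1$points$x, 1)

  # records missing the coordinate are skipped and counted
  with_na <- dplyr::bind_rows(full, tibble::tibble(bioink = "other",
                                                   t20 = 0, we = NA_real_,
                                                   re = 1, z = 1,
                                                   k_splash = 1))
  m2 <- build_map(classify_regimes(dplyr::mutate(
    with_na, z = ifelse(is.na(z), 1, z),
    k_splash = ifelse(is.na(k_splash), 1, k_splash))), "We_Re")
  expect_equal(m2$n_skipped, 1)

  expect_error(build_map(full, "Oh_f"), "'f'")
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(m1), "ggplot")
})

test_that("labels recomputed from coordinates equal stored labels", {
  tab <- classify_regimes(printed_conditions())
  tab <- tab[!is.na(tab$we) & !is.na(tab$re), ]
  m <- build_map(tab, "We_Re")
  z_from_coords <- m$points$y / sqrt(m$points$x) # Re / sqrt(We) = 1/Oh
  expect_equal(as.character(classify_z(z_from_coords)),
               as.character(m$points$z_class))
})
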