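test_that("age presets carry the measured densities and volumes", {
  e15 <- make_scenario("E15.5")
  expect_equal(e15$cortical_tec_density, 13)
  expect_equal(e15$medullary_tec_density, 23)

  p10 <- make_scenario("P10")
  expect_equal(p10$medullary_tec_density, 5)
  expect_equal(p10$organ_volume, 55.5)
  expect_equal(p10$section_thickness, 8)

  expect_equal(make_scenario("P28")$organ_volume, 130.3)
  expect_equal(make_scenario("E16.5")$organ_volume, 2.1)
  expect_equal(make_scenario("P0")$organ_volume, 10.6)

  expect_error(make_scenario("P99"), "E15.5.*P28|valid presets")
  custom <- make_scenario("custom", cortical_tec_density = 7, organ_volume = 3)
  expect_equal(custom$cortical_tec_density, 7)
  expect_equal(custom$organ_volume, 3)
  expect_error(make_scenario("custom", cortical_tec_density = -1), "densities")
  expect_error(make_scenario("custom", cortex_area_fraction = 1.5), "cortex_area_fraction")
})

test_that("zero densities give empty ground truth and background-only channels", {
  out <- render_section(empty_scenario(), c(150, 150), seed = 2)
  expect_equal(nrow(out$truth$tec), 0)
  expect_equal(nrow(out$truth$thymocytes), 0)
  for (ch in out$image$channels) {
    expect_gt(mean(ch), 95)
    expect_lt(mean(ch), 105)
    expect_lt(max(ch), 250)  # pure Poisson background, no blobs
  }
})

test_that("realized TEC counts are Poisson around density x area", {
  # 500x500 um full field at 13 per 1e4 um^2: expectation 325
  sc <- cortex_only_scenario(13)
  lambda <- 13 * 500 * 500 / 1e4
  expect_equal(lambda, 325)
  out <- render_section(sc, c(500, 500), seed = 11, image = FALSE,
                        full_field = TRUE)
  ci <- qpois(c(0.005, 0.995), lambda)
  expect_gte(nrow(out$truth$tec), ci[1])
  expect_lte(nrow(out$truth$tec), ci[2])
  expect_true(all(out$truth$tec$compartment == "cortex"))
})

test_that("rendering is a pure function of scenario, size and seed", {
  sc <- make_scenario("E15.5")
  a <- render_section(sc, c(200, 200), seed = 42)
  b <- render_section(sc, c(200, 200), seed = 42)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$tec, b$truth$tec)
  expect_identical(a$truth$compartment_map, b$truth$compartment_map)
  c_ <- render_section(sc, c(200, 200), seed = 43)
  expect_false(identical(a$truth$tec, c_$truth$tec))
})

test_that("centroid compartment labels agree with the compartment map", {
  out <- render_section(make_scenario("E15.5"), c(300, 300), seed = 5,
                        image = FALSE)
  for (df in list(out$truth$tec, out$truth$thymocytes)) {
    lab <- thymometry:::map_label_at(out$truth$compartment_map,
                                     df$x_um, df$y_um, out$truth$pixel_size_xy)
    expect_identical(thymometry:::comp_name(lab), df$compartment)
  }
})

test_that("hard-core separation holds and infeasible densities error", {
  sc <- cortex_only_scenario(20)
  out <- render_section(sc, c(250, 250), seed = 3, image = FALSE,
                        full_field = TRUE)
  tec <- out$truth$tec
  d <- as.matrix(dist(tec[, c("x_um", "y_um")]))
  diag(d) <- Inf
  expect_gte(min(d), sc$mean_nuclear_diameter)

  expect_error(
    render_section(cortex_only_scenario(2000), c(100, 100), seed = 1,
                   image = FALSE, full_field = TRUE),
    "packing limit"
  )
})

test_that("realized density converges to the requested density on large fields", {
  # >= 1e6 um^2, 20 seeds: seed-averaged relative error below 5%
  sc <- cortex_only_scenario(13)
  dens <- vapply(1:20, function(s) {
    out <- render_section(sc, c(1000, 1000), seed = s, image = FALSE,
                          full_field = TRUE)
    nrow(out$truth$tec) / 1e6 * 1e4
  }, numeric(1))
  expect_lt(abs(mean(dens) - 13) / 13, 0.05)
})

test_that("generator realizes the requested cortex area fraction within 2%", {
  sc <- make_scenario("custom", cortex_area_fraction = 0.8)
  out <- render_section(sc, c(500, 500), seed = 9, image = FALSE)
  fr <- area_fractions(out$truth$compartment_map,
                       pixel_size = out$truth$pixel_size_xy)
  expect_lt(abs(fr$cortex_fraction - 0.8), 0.02)
})

test_that("3D stacks are self-consistent and flag designed z-merge pairs", {
  sc0 <- empty_scenario()
  st <- render_stack(sc0, volume = c(40, 40, 20), seed = 1)
  expect_equal(nrow(st$truth$tec), 0)
  expect_lt(max(st$image$channels$nuclear_reporter), 250)

  # 100x100x50 um at 20 nuclei per 1e4 um^3; ground truth count is the
  # realized Poisson draw and identical across image/no-image renders
  sc <- cortex_only_scenario(13)
  a <- render_stack(sc, volume = c(100, 100, 50), seed = 4, image = FALSE,
                    thymocytes = FALSE, full_field = TRUE,
                    tec_density_volumetric = c(cortex = 20, medulla = 0))
  lambda <- 20 * 100 * 100 * 50 / 1e4
  ci <- qpois(c(0.0005, 0.9995), lambda)
  expect_gte(nrow(a$truth$tec), ci[1])
  expect_lte(nrow(a$truth$tec), ci[2])
  b <- render_stack(sc, volume = c(100, 100, 50), seed = 4, image = FALSE,
                    thymocytes = FALSE, full_field = TRUE,
                    tec_density_volumetric = c(cortex = 20, medulla = 0))
  expect_identical(a$truth$tec, b$truth$tec)

  # constructed hard case: two nuclei 0.4 um apart in z are recorded as a
  # z-merge case in the ground-truth metadata
  tec <- data.frame(x_um = c(10, 10, 30), y_um = c(10, 10, 30),
                    z_um = c(5, 5.4, 10))
  zm <- thymometry:::find_z_merge_cases(tec, axial_resolution = 6,
                                        lateral_radius = 3)
  expect_equal(nrow(zm), 1)
  expect_equal(zm$dz_um, 0.4, tolerance = 1e-12)
  expect_setequal(c(zm$i, zm$j), c(1, 2))
})
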