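make_uniform_mask <- function(code, n = 100, pixel_size = 1) {
  lab <- matrix(code, n, n)
  thymometry:::new_compartment_mask(lab, pixel_size)
}

test_that("compartment density is an exact count/area identity", {
  mask <- make_uniform_mask(1L)  # 100x100 um all cortex
  spots <- data.frame(x_um = seq(10, 90, length.out = 5),
                      y_um = seq(10, 90, length.out = 5))
  d <- compartment_density(spots, mask, "cortex")
  expect_equal(d$density, 5)  # 5 per 1e4 um^2
  expect_equal(d$tec_count, 5)
  expect_equal(d$density, d$tec_count / d$area * 1e4)

  d0 <- compartment_density(spots[0, ], mask, "cortex")
  expect_equal(d0$density, 0)
  expect_error(compartment_density(spots, mask, "medulla"), "zero medulla area")
})

test_that("cortical/medullary TEC ratio follows densities and fractions", {
  frac_eq <- list(cortex_fraction = 0.5, medulla_fraction = 0.5)
  expect_equal(ctec_mtec_ratio(5, 5, frac_eq)$ratio, 1)
  # the E15.5 configuration: ~3x more cortical than medullary TECs
  fr <- list(cortex_fraction = 0.84, medulla_fraction = 0.16)
  expect_equal(ctec_mtec_ratio(13, 23, fr)$ratio, (13 * 0.84) / (23 * 0.16))
  expect_equal(round(ctec_mtec_ratio(13, 23, fr)$ratio, 2), 2.97)
  expect_equal(ctec_mtec_ratio(1, 5, frac_eq)$ratio, 0.2)
  z <- ctec_mtec_ratio(1, 0, frac_eq)
  expect_true(z$degenerate)
  expect_equal(z$ratio, Inf)
})

test_that("thymopoietic index handles counts and fraction forms", {
  expect_equal(thymopoietic_index(tec_fraction = 0.001)$ti, 1000)
  expect_equal(thymopoietic_index(100, 100)$ti, 1)
  expect_equal(thymopoietic_index(6100, 100)$ti, 61)
  # count form (1-f)/f agrees with the inverse-fraction form within f
  f <- 0.001
  ti_counts <- thymopoietic_index(1 - f, f)$ti
  expect_lt(abs(ti_counts - 1 / f) / (1 / f), f * 1.01)
  expect_error(thymopoietic_index(10, 0), "tec_count")
  expect_error(thymopoietic_index(tec_fraction = 0), "tec_fraction")
  expect_error(thymopoietic_index(tec_fraction = 2), "tec_fraction")
})

test_that("whole-organ TI is the TEC-weighted combination of compartment TIs", {
  expect_equal(whole_organ_ti(50, 50, c(0.3, 0.7))$ti, 50)
  expect_equal(whole_organ_ti(100, 20, c(0.5, 0.5))$ti, 60)
  expect_equal(whole_organ_ti(100, 20, c(1, 0))$ti, 100)
  # weighting by TEC counts reproduces total thymocytes / total TECs
  ti_c <- thymopoietic_index(900, 30, scope = "cortex")
  ti_m <- thymopoietic_index(200, 20, scope = "medulla")
  expect_equal(whole_organ_ti(ti_c, ti_m, c(30, 20))$ti, (900 + 200) / 50)
  expect_error(whole_organ_ti(1, 2, c(0, 0)), "tec_weights")
})

test_that("stereological extrapolation matches the arithmetic oracle", {
  sc <- make_scenario("P10")
  fr <- list(cortex_fraction = 0.5, medulla_fraction = 0.5)
  st <- extrapolate_total_tecs(0.9, 5, fr, sc)
  # oracle: ((0.9 + 5)e-4 / (8 + 6) um) * 0.5 * 55.5e9 um^3
  expect_equal(st$total_tec_estimate, 5.9e-4 / 14 * 0.5 * 55.5e9)
  expect_equal(st$total_tec_estimate, 1169464.2857, tolerance = 1e-8)
  expect_equal(st$total_tec_estimate,
               sum(st$compartment_totals))

  z <- extrapolate_total_tecs(0, 0, fr, sc)
  expect_equal(z$total_tec_estimate, 0)

  sc2 <- sc; sc2$organ_volume <- 2 * sc$organ_volume
  expect_equal(extrapolate_total_tecs(0.9, 5, fr, sc2)$total_tec_estimate,
               2 * st$total_tec_estimate)

  none <- extrapolate_total_tecs(0.9, 5, fr, sc, correction = "none")
  expect_equal(none$effective_thickness, c(8, 8))
  expect_gt(none$total_tec_estimate, st$total_tec_estimate)

  per_comp <- extrapolate_total_tecs(0.9, 5, fr, sc,
                                     effective_thickness = c(14, 16))
  expect_equal(per_comp$volumetric_density[["medulla"]], 5e-4 / 16)
})

test_that("reconciliation identities hold exactly", {
  r <- reconcile(61, 810, 1.12e5)
  expect_equal(r$correction_factor, 810 / 61)
  expect_equal(round(r$correction_factor, 1), 13.3)
  expect_equal(r$corrected_total, 1.12e5 * 810 / 61)
  expect_equal(r$correction_factor * r$recovery_rate, 1, tolerance = 1e-12)
  expect_true(r$recovery_in_range)

  r13 <- reconcile(61, 61 * 13, 1.12e5)
  expect_equal(r13$corrected_total, 1.456e6)

  same <- reconcile(50, 50, 1000)
  expect_equal(same$correction_factor, 1)
  expect_equal(same$recovery_rate, 1)

  ri <- reconcile(61, 810, 1.12e5, insitu_tec_count = 1.5e6)
  expect_equal(ri$recovery_rate, 1.12e5 / 1.5e6)
  expect_identical(ri$recovery_basis, "insitu_count")

  expect_error(reconcile(0, 810, 1), "ti_hist")
  expect_error(reconcile(61, -1, 1), "ti_flow")
})

test_that("fold changes reproduce the perinatal TI increases", {
  expect_equal(fold_change(61, 23), 61 / 23)
  expect_equal(round(fold_change(61, 23), 1), 2.7)
  expect_equal(fold_change(810, 216), 3.75)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(1, 0), "denominator")
})

test_that("all ratio operations are invariant under count rescaling", {
  for (k in c(2, 10, 1000)) {
    expect_equal(thymopoietic_index(6100 * k, 100 * k)$ti, 61)
    expect_equal(whole_organ_ti(100, 20, k * c(30, 20))$ti,
                 whole_organ_ti(100, 20, c(30, 20))$ti)
    expect_equal(fold_change(810 * k, 216 * k), 3.75)
    r <- reconcile(61, 810, 1.12e5 * k)
    expect_equal(r$correction_factor, 810 / 61)
  }
})

test_that("extrapolation recovers the generator's implied organ totals", {
  # lossless counting: densities measured from ground truth directly,
  # pooled over sections (single low-density sections are Poisson-noisy)
  for (age in c("E15.5", "P10")) {
    sc <- make_scenario(age)
    counts <- c(cortex = 0, medulla = 0)
    areas <- c(cortex = 0, medulla = 0)
    fr_sum <- 0
    for (s in 1:5) {
      out <- render_section(sc, c(600, 600), seed = 20 + s, image = FALSE)
      mask <- thymometry:::new_compartment_mask(out$truth$compartment_map,
                                                out$truth$pixel_size_xy)
      fr_sum <- fr_sum + area_fractions(mask)$cortex_fraction
      for (comp in c("cortex", "medulla")) {
        d <- compartment_density(out$truth$tec, mask, comp)
        counts[comp] <- counts[comp] + d$tec_count
        areas[comp] <- areas[comp] + d$area
      }
    }
    fr <- list(cortex_fraction = fr_sum / 5, medulla_fraction = 1 - fr_sum / 5)
    st <- extrapolate_total_tecs(counts[["cortex"]] / areas[["cortex"]] * 1e4,
                                 counts[["medulla"]] / areas[["medulla"]] * 1e4,
                                 fr, sc)
    implied <- extrapolate_total_tecs(
      sc$cortical_tec_density, sc$medullary_tec_density,
      list(cortex_fraction = sc$cortex_area_fraction,
           medulla_fraction = 1 - sc$cortex_area_fraction), sc
    )
    expect_lt(abs(st$total_tec_estimate - implied$total_tec_estimate) /
                implied$total_tec_estimate, 0.1)
  }
})
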