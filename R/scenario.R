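#' Tissue scenarios for the developing thymus
#'
#' A `tissue_scenario` bundles the physical and cytological parameters of
#' the thymus at a given developmental age: per-compartment TEC nuclear
#' densities, the cortical area fraction, thymocyte densities (which set the
#' DAPI appearance and the section-level thymopoietic index), organ volume,
#' cryosection thickness, mean TEC nuclear diameter, and imaging pixel
#' sizes. Presets encode the measured values for mouse thymi at E15.5,
#' E16.5, P0, P10 and P28; where a quantity was not measured directly the
#' preset back-derives it from published ratios (see the methods vignette).
#'
#' Thymocyte densities in presets are back-derived as
#' `TI x TEC density` from per-compartment thymopoietic indices, since
#' section-level thymocyte densities were not reported directly.
#'
#' @param age_label one of `"E15.5"`, `"E16.5"`, `"P0"`, `"P10"`, `"P28"`,
#'   or `"custom"` (all parameters must then be supplied via `...`).
#' @param ... for `"custom"`, explicit values for any scenario field.
#'
#' @return An object of class `tissue_scenario`: a list with fields
#'   `age_label`, `cortical_tec_density`, `medullary_tec_density`
#'   (counts per 1e4 um^2), `cortex_area_fraction`,
#'   `thymocyte_density_cortex`, `thymocyte_density_medulla`
#'   (counts per 1e4 um^2), `organ_volume` (ul), `section_thickness` (um),
#'   `mean_nuclear_diameter` (um), `pixel_size_xy`, `pixel_size_z` (um),
#'   `foxn1_negative_fraction`.
#'
#' @examples
#' sc <- make_scenario("E15.5")
#' sc$cortical_tec_density   # 13 per 1e4 um^2
#' sc$medullary_tec_density  # 23 per 1e4 um^2
#' @export
make_scenario <- function(age_label, ...) {
  presets <- scenario_presets()
  if (identical(age_label, "custom")) {
    sc <- utils::modifyList(presets[["P10"]], list(age_label = "custom", ...))
    return(validate_scenario(structure(sc, class = "tissue_scenario")))
  }
  if (!age_label %in% names(presets)) {
    stop(sprintf(
      "unknown age preset '%s'; valid presets: %s, or 'custom'",
      age_label, paste(names(presets), collapse = ", ")
    ), call. = FALSE)
  }
  sc <- utils::modifyList(presets[[age_label]], list(...))
  validate_scenario(structure(sc, class = "tissue_scenario"))
}

# Preset sources: TEC densities and organ volumes as measured; cortex area
# fractions and per-compartment thymopoietic indices back-derived so that
# cortical/medullary TEC count ratios (~3 at E15.5, ~1 at P10) and
# whole-organ TIs (~23 at P0, ~61 at P10) are reproduced. P28 densities
# back-derived so the stereological whole-organ total at 130.3 ul lands on
# the ~1.5e6 scale. Details in the methods vignette.
scenario_presets <- function() {
  base <- list(
    section_thickness = 8, mean_nuclear_diameter = 6,
    pixel_size_xy = 0.645, pixel_size_z = NA_real_,
    foxn1_negative_fraction = 0
  )
  mk <- function(age, dc, dm, fc, tic, tim, vol) {
    utils::modifyList(base, list(
      age_label = age,
      cortical_tec_density = dc, medullary_tec_density = dm,
      cortex_area_fraction = fc,
      thymocyte_density_cortex = tic * dc,
      thymocyte_density_medulla = tim * dm,
      organ_volume = vol
    ))
  }
  list(
    "E15.5" = mk("E15.5", 13,  23,  0.84,  16,  2,  0.9),
    "E16.5" = mk("E16.5", 10,  18,  0.84,  20,  3,  2.1),
    "P0"    = mk("P0",     2,   8,  0.82,  36,  8, 10.6),
    "P10"   = mk("P10",  0.9,   5, 0.854, 100, 20, 55.5),
    "P28"   = mk("P28",  0.8, 4.5,  0.80, 120, 25, 130.3)
  )
}

validate_scenario <- function(sc) {
  dens <- c(
    sc$cortical_tec_density, sc$medullary_tec_density,
    sc$thymocyte_density_cortex, sc$thymocyte_density_medulla
  )
  if (any(!is.finite(dens)) || any(dens < 0)) {
    stop("all densities must be finite and >= 0", call. = FALSE)
  }
  if (sc$cortex_area_fraction < 0 || sc$cortex_area_fraction > 1) {
    stop("cortex_area_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(sc$organ_volume) || sc$organ_volume <= 0) {
    stop("organ_volume must be > 0", call. = FALSE)
  }
  if (sc$section_thickness <= 0) stop("section_thickness must be > 0", call. = FALSE)
  if (sc$mean_nuclear_diameter <= 0) stop("mean_nuclear_diameter must be > 0", call. = FALSE)
  if (sc$foxn1_negative_fraction < 0 || sc$foxn1_negative_fraction > 1) {
    stop("foxn1_negative_fraction must lie in [0, 1]", call. = FALSE)
  }
  sc
}

#' @export
print.tissue_scenario <- function(x, ...) {
  cat(sprintf("<tissue_scenario %s>\n", x$age_label))
  cat(sprintf("  TEC density (per 1e4 um^2): cortex %.3g, medulla %.3g\n",
              x$cortical_tec_density, x$medullary_tec_density))
  cat(sprintf("  thymocyte density:          cortex %.3g, medulla %.3g\n",
              x$thymocyte_density_cortex, x$thymocyte_density_medulla))
  cat(sprintf("  cortex area fraction %.3g | organ volume %.4g ul\n",
              x$cortex_area_fraction, x$organ_volume))
  cat(sprintf("  section %g um | nuclear diameter %g um | pixel %g um/px\n",
              x$section_thickness, x$mean_nuclear_diameter, x$pixel_size_xy))
  invisible(x)
}
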