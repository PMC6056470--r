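# fixture builders shared across test files; all synthetic, generated at
# test time

# single-compartment scenario with explicit densities and no thymocytes:
# the workhorse for detector calibration
cortex_only_scenario <- function(tec_density, thymocyte_density = 0) {
  make_scenario(
    "custom",
    cortical_tec_density = tec_density, medullary_tec_density = 0,
    cortex_area_fraction = 1,
    thymocyte_density_cortex = thymocyte_density,
    thymocyte_density_medulla = 0
  )
}

empty_scenario <- function() {
  make_scenario(
    "custom",
    cortical_tec_density = 0, medullary_tec_density = 0,
    thymocyte_density_cortex = 0, thymocyte_density_medulla = 0
  )
}

# stack fixture with isolated nuclei plus one designed z-merge pair
# (axial gap below the axial blur sigma of 3 um)
zmerge_fixture <- function(dz = 2) {
  iso <- expand.grid(x_um = seq(8, 52, length.out = 4),
                     y_um = seq(8, 52, length.out = 3))
  iso$z_um <- 14
  pair <- data.frame(x_um = c(30.5, 30.5), y_um = c(30.5, 30.5),
                     z_um = c(6, 6 + dz))
  coords <- rbind(iso, pair)
  list(coords = coords,
       image = render_points_stack(coords, volume = c(60, 60, 28)))
}
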