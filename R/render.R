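#' @name imgen
#' @title Synthetic thymus section and stack generator
#' @description
#' The generator draws a smooth tissue blob with an outer cortical shell and
#' an inner medullary island (random low-order radial harmonics), places TEC
#' and thymocyte nuclei by a hard-core point process at the scenario's
#' per-compartment densities, and renders them as Gaussian blobs over a
#' Poisson-noise background. Every placement is recorded as ground truth so
#' downstream detection, segmentation and morphometry can be scored exactly.
NULL

COMP_OUTSIDE <- 0L
COMP_CORTEX  <- 1L
COMP_MEDULLA <- 2L

# thymocyte nuclei are smaller than TEC nuclei; fixed diameter in um
THYMOCYTE_DIAMETER <- 4.5

BACKGROUND_MEAN <- 100
PEAK_OVER_BACKGROUND <- 10        # blob peak = 10x background
AMPLITUDE_SD_LOG10 <- 0.1         # cell-to-cell reporter variation

radial_boundary <- function(n_theta = 720L, k_max = 5L, amp_sd = 0.03) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  mod <- rep(1, n_theta)
  for (k in 2:k_max) {
    mod <- mod + rnorm(1, 0, amp_sd) * cos(k * th) + rnorm(1, 0, amp_sd) * sin(k * th)
  }
  list(theta = th, mod = pmax(mod, 0.5))
}

interp_radius <- function(bnd, theta) {
  n <- length(bnd$theta)
  idx <- (theta %% (2 * pi)) / (2 * pi) * n
  i0 <- floor(idx)
  fr <- idx - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  bnd$mod[i0] * (1 - fr) + bnd$mod[i1] * fr
}

# cortex = outer shell, medulla = inner island; medulla radius rescaled by
# pixel counting until its share of tissue area is within 2% of target
make_compartment_map <- function(field_size, pixel_size, cortex_fraction,
                                 full_field = FALSE) {
  nx <- max(2L, round(field_size[1] / pixel_size))
  ny <- max(2L, round(field_size[2] / pixel_size))
  cx <- field_size[1] / 2
  cy <- field_size[2] / 2
  xs <- (seq_len(nx) - 0.5) * pixel_size
  ys <- (seq_len(ny) - 0.5) * pixel_size
  dx <- matrix(xs - cx, nx, ny)
  dy <- matrix(ys - cy, nx, ny, byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)

  if (full_field) {
    tissue <- matrix(TRUE, nx, ny)
    r_tis <- 0.5 * min(field_size)
  } else {
    bt <- radial_boundary(amp_sd = 0.03)
    r_tis <- 0.46 * min(field_size)
    tissue <- r < r_tis * interp_radius(bt, th)
  }

  map <- matrix(COMP_OUTSIDE, nx, ny)
  map[tissue] <- COMP_CORTEX
  med_target <- (1 - cortex_fraction) * sum(tissue)
  if (med_target > 0.5) {
    bm <- radial_boundary(k_max = 4L, amp_sd = 0.05)
    mx <- cx + rnorm(1, 0, 0.04 * r_tis)
    my <- cy + rnorm(1, 0, 0.04 * r_tis)
    dmx <- matrix(xs - mx, nx, ny)
    dmy <- matrix(ys - my, nx, ny, byrow = TRUE)
    rm_ <- sqrt(dmx^2 + dmy^2)
    thm <- atan2(dmy, dmx)
    modm <- interp_radius(bm, thm)
    r_med <- sqrt(med_target * pixel_size^2 / pi)
    for (it in 1:6) {
      med <- tissue & (rm_ < r_med * modm)
      got <- sum(med)
      if (got > 0 && abs(got - med_target) / med_target < 0.015) break
      r_med <- r_med * sqrt(med_target / max(got, 1))
    }
    map[med] <- COMP_MEDULLA
  }
  map
}

# sequential hard-core sampler with a cell grid; n is fixed (caller draws
# it Poisson), proposals uniform over `allowed` pixels with sub-pixel jitter
place_hardcore <- function(n, allowed, pixel_size, min_sep,
                           z_range = NULL, existing = NULL) {
  if (n == 0) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0))
    if (!is.null(z_range)) out$z_um <- numeric(0)
    return(out)
  }
  idx <- which(allowed)
  if (length(idx) == 0) stop("no admissible pixels for placement", call. = FALSE)
  nx <- nrow(allowed)
  cell <- max(min_sep, 1e-6)
  grid <- new.env(parent = emptyenv(), hash = TRUE)
  gkey <- function(gx, gy, gz) paste(gx, gy, gz, sep = ",")
  three_d <- !is.null(z_range)
  pts <- matrix(NA_real_, n, if (three_d) 3L else 2L)
  add_to_grid <- function(p, label) {
    g <- floor(p / cell)
    key <- gkey(g[1], g[2], if (three_d) g[3] else 0L)
    grid[[key]] <- rbind(grid[[key]] %||% NULL, p)
  }
  if (!is.null(existing) && nrow(existing) > 0) {
    for (i in seq_len(nrow(existing))) add_to_grid(as.numeric(existing[i, ]), i)
  }
  conflict <- function(p) {
    g <- floor(p / cell)
    zr <- if (three_d) (g[3] - 1L):(g[3] + 1L) else 0L
    for (gx in (g[1] - 1L):(g[1] + 1L)) for (gy in (g[2] - 1L):(g[2] + 1L)) for (gz in zr) {
      q <- grid[[gkey(gx, gy, gz)]]
      if (!is.null(q)) {
        d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2
        if (three_d) d2 <- d2 + (q[, 3] - p[3])^2
        if (any(d2 < min_sep^2)) return(TRUE)
      }
    }
    FALSE
  }
  area <- length(idx) * pixel_size^2
  placed <- 0L
  attempts <- 0L
  budget <- 40L * n + 2000L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > budget) {
      # random sequential adsorption jamming limits: discs in 2D, spheres in 3D
      limit <- if (three_d) {
        0.382 * area * diff(z_range) / (4 / 3 * pi * (min_sep / 2)^3)
      } else {
        0.547 * area / (pi * (min_sep / 2)^2)
      }
      stop(sprintf(
        "hard-core placement infeasible: requested %d points, packing limit ~%.0f for min separation %.2g um",
        n, limit, min_sep
      ), call. = FALSE)
    }
    pix <- idx[sample.int(length(idx), 1L)]
    i <- ((pix - 1L) %% nx) + 1L
    j <- ((pix - 1L) %/% nx) + 1L
    p <- c((i - 1L + runif(1)) * pixel_size, (j - 1L + runif(1)) * pixel_size)
    if (three_d) p <- c(p, runif(1, z_range[1], z_range[2]))
    if (!conflict(p)) {
      placed <- placed + 1L
      pts[placed, ] <- p
      add_to_grid(p, placed)
    }
  }
  out <- data.frame(x_um = pts[, 1], y_um = pts[, 2])
  if (three_d) out$z_um <- pts[, 3]
  out
}

map_label_at <- function(map, x_um, y_um, pixel_size) {
  nx <- nrow(map); ny <- ncol(map)
  i <- pmin(pmax(floor(x_um / pixel_size) + 1L, 1L), nx)
  j <- pmin(pmax(floor(y_um / pixel_size) + 1L, 1L), ny)
  map[cbind(i, j)]
}

comp_name <- function(code) {
  c("outside", "cortex", "medulla")[code + 1L]
}

stamp_blobs_2d <- function(img, x_px, y_px, amp, sigma_px) {
  if (length(x_px) == 0) return(img)
  nx <- nrow(img); ny <- ncol(img)
  r <- ceiling(3 * sigma_px)
  off <- seq(-r, r)
  for (b in seq_along(x_px)) {
    ci <- x_px[b]; cj <- y_px[b]
    ii <- round(ci) + off; jj <- round(cj) + off
    ki <- ii >= 1 & ii <= nx; kj <- jj >= 1 & jj <= ny
    if (!any(ki) || !any(kj)) next
    gx <- exp(-((ii[ki] - ci)^2) / (2 * sigma_px^2))
    gy <- exp(-((jj[kj] - cj)^2) / (2 * sigma_px^2))
    img[ii[ki], jj[kj]] <- img[ii[ki], jj[kj]] + amp[b] * outer(gx, gy)
  }
  img
}

stamp_blobs_3d <- function(arr, x_px, y_px, z_px, amp, sigma_px_xy, sigma_px_z) {
  if (length(x_px) == 0) return(arr)
  d <- dim(arr)
  r <- ceiling(3 * sigma_px_xy); rz <- ceiling(3 * sigma_px_z)
  off <- seq(-r, r); offz <- seq(-rz, rz)
  for (b in seq_along(x_px)) {
    ci <- x_px[b]; cj <- y_px[b]; ck <- z_px[b]
    ii <- round(ci) + off; jj <- round(cj) + off; kk <- round(ck) + offz
    ki <- ii >= 1 & ii <= d[1]; kj <- jj >= 1 & jj <= d[2]; kz <- kk >= 1 & kk <= d[3]
    if (!any(ki) || !any(kj) || !any(kz)) next
    gx <- exp(-((ii[ki] - ci)^2) / (2 * sigma_px_xy^2))
    gy <- exp(-((jj[kj] - cj)^2) / (2 * sigma_px_xy^2))
    gz <- exp(-((kk[kz] - ck)^2) / (2 * sigma_px_z^2))
    patch <- amp[b] * outer(gx, gy) %o% gz
    arr[ii[ki], jj[kj], kk[kz]] <- arr[ii[ki], jj[kj], kk[kz]] + patch
  }
  arr
}

new_section_image <- function(channels, pixel_size_xy, pixel_size_z = NA_real_,
                              thickness = NA_real_) {
  structure(
    list(channels = channels, pixel_size_xy = pixel_size_xy,
         pixel_size_z = pixel_size_z, thickness = thickness),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<section_image %s: %s px @ %g um/px%s>\n",
              paste(names(x$channels), collapse = "+"),
              paste(d, collapse = "x"), x$pixel_size_xy,
              if (!is.na(x$pixel_size_z)) sprintf(" (z %g)", x$pixel_size_z) else ""))
  invisible(x)
}

new_ground_truth <- function(tec, thymocytes, compartment_map, pixel_size_xy,
                             field_size, z_merge_cases = NULL) {
  structure(
    list(tec = tec, thymocytes = thymocytes, compartment_map = compartment_map,
         pixel_size_xy = pixel_size_xy, field_size = field_size,
         z_merge_cases = z_merge_cases),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d TEC, %d thymocyte nuclei>\n",
              nrow(x$tec), nrow(x$thymocytes)))
  invisible(x)
}

#' Render a synthetic two-reporter thymus cryosection
#'
#' Draws a tissue blob with cortical shell and medullary island at the
#' scenario's cortex area fraction (realized within 2%), places TEC nuclei
#' by a hard-core point process (minimum separation = mean nuclear
#' diameter, realized counts Poisson around density x area) in each
#' compartment, thymocyte nuclei likewise, and renders Gaussian nuclear
#' blobs (sigma = diameter/4, peak 10x a background of 100, per-cell
#' log-normal brightness variation, Poisson shot noise). The
#' `nuclear_reporter` channel carries reporter-positive TEC nuclei only;
#' `dapi` carries all nuclei.
#'
#' @param scenario a [make_scenario()] object.
#' @param field_size numeric length-2, field width and height in um.
#' @param seed integer seed; rendering is a pure function of
#'   (scenario, field_size, seed).
#' @param image if `FALSE`, skip rasterization and return only ground truth
#'   (fast path for count statistics).
#' @param full_field if `TRUE`, tissue fills the whole field (no outside
#'   background); useful for density calibration fixtures.
#' @param amplitude_sd_log10 per-cell brightness variation (log10 sd).
#' @return A list with elements `image` (a `section_image`, or `NULL`) and
#'   `truth` (a `ground_truth` with TEC/thymocyte centroids, compartment
#'   labels agreeing with the compartment map, and the map itself).
#' @examples
#' sc <- make_scenario("E15.5")
#' out <- render_section(sc, field_size = c(200, 200), seed = 1)
#' nrow(out$truth$tec)
#' @export
render_section <- function(scenario, field_size = c(500, 500), seed = 1L,
                           image = TRUE, full_field = FALSE,
                           amplitude_sd_log10 = AMPLITUDE_SD_LOG10) {
  stopifnot(length(field_size) == 2, all(field_size > 0))
  validate_scenario(scenario)
  set.seed(as.integer(seed))
  ps <- scenario$pixel_size_xy
  map <- make_compartment_map(field_size, ps, scenario$cortex_area_fraction,
                              full_field = full_field)
  px_area <- ps^2

  draw_pop <- function(dens_c, dens_m, min_sep, existing = NULL) {
    res <- list()
    for (comp in c(COMP_CORTEX, COMP_MEDULLA)) {
      dens <- if (comp == COMP_CORTEX) dens_c else dens_m
      allowed <- map == comp
      area <- sum(allowed) * px_area
      lambda <- dens * area / 1e4
      n <- if (lambda > 0) rpois(1, lambda) else 0L
      pts <- place_hardcore(n, allowed, ps, min_sep, existing = existing)
      existing <- rbind(existing, pts[, c("x_um", "y_um")])
      res[[length(res) + 1L]] <- pts
    }
    do.call(rbind, res)
  }

  tec <- draw_pop(scenario$cortical_tec_density, scenario$medullary_tec_density,
                  scenario$mean_nuclear_diameter)
  thy <- draw_pop(scenario$thymocyte_density_cortex,
                  scenario$thymocyte_density_medulla, THYMOCYTE_DIAMETER)
  tec$compartment <- comp_name(map_label_at(map, tec$x_um, tec$y_um, ps))
  thy$compartment <- comp_name(map_label_at(map, thy$x_um, thy$y_um, ps))
  fneg <- scenario$foxn1_negative_fraction
  tec$reporter_positive <- if (nrow(tec) > 0) runif(nrow(tec)) >= fneg else logical(0)

  truth <- new_ground_truth(tec, thy, map, ps, field_size)
  if (!image) return(list(image = NULL, truth = truth))

  sig_tec <- scenario$mean_nuclear_diameter / 4 / ps
  sig_thy <- THYMOCYTE_DIAMETER / 4 / ps
  amp0 <- BACKGROUND_MEAN * (PEAK_OVER_BACKGROUND - 1)
  amp_of <- function(n) amp0 * 10^rnorm(n, 0, amplitude_sd_log10)

  base <- matrix(BACKGROUND_MEAN, nrow(map), ncol(map))
  tec_amp <- amp_of(nrow(tec))
  thy_amp <- amp_of(nrow(thy))
  pos <- tec$reporter_positive
  nuc <- stamp_blobs_2d(base, tec$x_um[pos] / ps + 0.5, tec$y_um[pos] / ps + 0.5,
                        tec_amp[pos], sig_tec)
  dapi <- stamp_blobs_2d(base, tec$x_um / ps + 0.5, tec$y_um / ps + 0.5,
                         tec_amp, sig_tec)
  dapi <- stamp_blobs_2d(dapi, thy$x_um / ps + 0.5, thy$y_um / ps + 0.5,
                         thy_amp, sig_thy)
  shot <- function(m) matrix(rpois(length(m), m), nrow(m), ncol(m))
  img <- new_section_image(
    list(nuclear_reporter = shot(nuc), dapi = shot(dapi)),
    pixel_size_xy = ps, thickness = scenario$section_thickness
  )
  list(image = img, truth = truth)
}

#' Render a synthetic anisotropic 3D light-sheet stack
#'
#' As [render_section()] but volumetric: the cortical/medullary geometry is
#' extruded along z, nuclei are placed with a 3D hard-core constraint, and
#' blobs are blurred twice as much axially as laterally to emulate the
#' light-sheet z-merging failure mode. Volumetric densities default to the
#' scenario's areal densities divided by the Abercrombie effective
#' thickness (section thickness + nuclear diameter).
#'
#' @inheritParams render_section
#' @param volume numeric length-3, physical size in um (x, y, z).
#' @param voxel_size_xy,voxel_size_z voxel pitch in um (light-sheet
#'   defaults 0.229 and 0.589).
#' @param tec_density_volumetric optional per-compartment volumetric TEC
#'   densities, counts per 1e4 um^3, named `cortex` and `medulla`.
#' @param thymocytes include thymocyte nuclei in the DAPI channel.
#' @return As [render_section()]; ground-truth centroids carry `z_um`, and
#'   `truth$z_merge_cases` lists designed hard-case pairs closer axially
#'   than the axial resolution (2 x axial blob sigma) and laterally than
#'   half a nuclear diameter.
#' @export
render_stack <- function(scenario, volume = c(60, 60, 24), seed = 1L,
                         voxel_size_xy = 0.229, voxel_size_z = 0.589,
                         tec_density_volumetric = NULL,
                         thymocytes = TRUE, image = TRUE, full_field = FALSE,
                         amplitude_sd_log10 = AMPLITUDE_SD_LOG10) {
  stopifnot(length(volume) == 3, all(volume > 0))
  validate_scenario(scenario)
  set.seed(as.integer(seed))
  eff_t <- scenario$section_thickness + scenario$mean_nuclear_diameter
  if (is.null(tec_density_volumetric)) {
    tec_density_volumetric <- c(
      cortex = scenario$cortical_tec_density / eff_t,
      medulla = scenario$medullary_tec_density / eff_t
    )
  }
  thy_density_volumetric <- c(
    cortex = scenario$thymocyte_density_cortex / (scenario$section_thickness + THYMOCYTE_DIAMETER),
    medulla = scenario$thymocyte_density_medulla / (scenario$section_thickness + THYMOCYTE_DIAMETER)
  )
  ps <- voxel_size_xy
  map <- make_compartment_map(volume[1:2], ps, scenario$cortex_area_fraction,
                              full_field = full_field)
  px_area <- ps^2

  draw_pop3 <- function(dens, min_sep, existing = NULL) {
    res <- list()
    for (comp in c(COMP_CORTEX, COMP_MEDULLA)) {
      dv <- dens[[comp_name(comp)]]
      allowed <- map == comp
      vol_comp <- sum(allowed) * px_area * volume[3]
      lambda <- dv * vol_comp / 1e4
      n <- if (lambda > 0) rpois(1, lambda) else 0L
      pts <- place_hardcore(n, allowed, ps, min_sep,
                            z_range = c(0, volume[3]), existing = existing)
      existing <- rbind(existing, pts[, c("x_um", "y_um", "z_um")])
      res[[length(res) + 1L]] <- pts
    }
    do.call(rbind, res)
  }

  tec <- draw_pop3(tec_density_volumetric, scenario$mean_nuclear_diameter)
  thy <- if (thymocytes) draw_pop3(thy_density_volumetric, THYMOCYTE_DIAMETER) else {
    data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0))
  }
  tec$compartment <- comp_name(map_label_at(map, tec$x_um, tec$y_um, ps))
  thy$compartment <- comp_name(map_label_at(map, thy$x_um, thy$y_um, ps))
  tec$reporter_positive <- if (nrow(tec) > 0) {
    runif(nrow(tec)) >= scenario$foxn1_negative_fraction
  } else logical(0)

  sig_xy <- scenario$mean_nuclear_diameter / 4
  zmc <- find_z_merge_cases(tec, axial_resolution = 2 * (2 * sig_xy),
                            lateral_radius = scenario$mean_nuclear_diameter / 2)
  truth <- new_ground_truth(tec, thy, map, ps, volume, z_merge_cases = zmc)
  if (!image) return(list(image = NULL, truth = truth))

  img <- rasterize_stack(tec, thy, dims = c(nrow(map), ncol(map),
                                            max(2L, round(volume[3] / voxel_size_z))),
                         voxel_size_xy = voxel_size_xy, voxel_size_z = voxel_size_z,
                         sigma_xy = sig_xy, sigma_z = 2 * sig_xy,
                         sigma_thy = THYMOCYTE_DIAMETER / 4,
                         amplitude_sd_log10 = amplitude_sd_log10)
  list(image = img, truth = truth)
}

find_z_merge_cases <- function(tec, axial_resolution, lateral_radius) {
  n <- nrow(tec)
  if (n < 2 || is.null(tec$z_um)) return(NULL)
  out <- list()
  for (i in seq_len(n - 1)) {
    dxy <- sqrt((tec$x_um[-seq_len(i)] - tec$x_um[i])^2 +
                (tec$y_um[-seq_len(i)] - tec$y_um[i])^2)
    dz <- abs(tec$z_um[-seq_len(i)] - tec$z_um[i])
    hit <- which(dxy < lateral_radius & dz < axial_resolution)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        i = i, j = i + hit, dz_um = dz[hit], dxy_um = dxy[hit]
      )
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

rasterize_stack <- function(tec, thy, dims, voxel_size_xy, voxel_size_z,
                            sigma_xy, sigma_z, sigma_thy,
                            amplitude_sd_log10 = AMPLITUDE_SD_LOG10) {
  amp0 <- BACKGROUND_MEAN * (PEAK_OVER_BACKGROUND - 1)
  amp_of <- function(n) amp0 * 10^rnorm(n, 0, amplitude_sd_log10)
  base <- array(BACKGROUND_MEAN, dims)
  tec_amp <- amp_of(nrow(tec))
  thy_amp <- amp_of(nrow(thy))
  pos <- tec$reporter_positive %||% rep(TRUE, nrow(tec))
  to_px <- function(v, p) v / p + 0.5
  nuc <- stamp_blobs_3d(base, to_px(tec$x_um[pos], voxel_size_xy),
                        to_px(tec$y_um[pos], voxel_size_xy),
                        to_px(tec$z_um[pos], voxel_size_z),
                        tec_amp[pos], sigma_xy / voxel_size_xy, sigma_z / voxel_size_z)
  dapi <- stamp_blobs_3d(base, to_px(tec$x_um, voxel_size_xy),
                         to_px(tec$y_um, voxel_size_xy),
                         to_px(tec$z_um, voxel_size_z),
                         tec_amp, sigma_xy / voxel_size_xy, sigma_z / voxel_size_z)
  if (nrow(thy) > 0) {
    dapi <- stamp_blobs_3d(dapi, to_px(thy$x_um, voxel_size_xy),
                           to_px(thy$y_um, voxel_size_xy),
                           to_px(thy$z_um, voxel_size_z),
                           thy_amp, sigma_thy / voxel_size_xy,
                           2 * sigma_thy / voxel_size_z)
  }
  shot <- function(a) array(rpois(length(a), a), dim(a))
  new_section_image(list(nuclear_reporter = shot(nuc), dapi = shot(dapi)),
                    pixel_size_xy = voxel_size_xy, pixel_size_z = voxel_size_z)
}

#' Render an image from an explicit list of nuclear positions
#'
#' Fixture builders: render the `nuclear_reporter` (and `dapi`) channel from
#' caller-supplied centroids instead of a random point process. Used to
#' construct deterministic hard cases (known centroids, designed z-merge
#' pairs) for detector tests.
#'
#' @param coords data frame with `x_um`, `y_um` (and `z_um` for stacks);
#'   optional `amplitude` column (blob peak over background, default 900).
#' @param field_size,volume physical extent in um.
#' @param pixel_size,voxel_size_xy,voxel_size_z pitch in um.
#' @param nuclear_diameter blob diameter in um (sigma = diameter/4; axial
#'   sigma doubled in stacks).
#' @param noise add Poisson shot noise.
#' @return A `section_image`.
#' @export
render_points_section <- function(coords, field_size, pixel_size = 0.645,
                                  nuclear_diameter = 6, noise = TRUE) {
  nx <- max(2L, round(field_size[1] / pixel_size))
  ny <- max(2L, round(field_size[2] / pixel_size))
  amp <- coords$amplitude %||% rep(BACKGROUND_MEAN * (PEAK_OVER_BACKGROUND - 1), nrow(coords))
  img <- stamp_blobs_2d(matrix(BACKGROUND_MEAN, nx, ny),
                        coords$x_um / pixel_size + 0.5, coords$y_um / pixel_size + 0.5,
                        amp, nuclear_diameter / 4 / pixel_size)
  if (noise) img <- matrix(rpois(length(img), img), nx, ny)
  new_section_image(list(nuclear_reporter = img, dapi = img),
                    pixel_size_xy = pixel_size)
}

#' @rdname render_points_section
#' @export
render_points_stack <- function(coords, volume, voxel_size_xy = 0.229,
                                voxel_size_z = 0.589, nuclear_diameter = 6,
                                noise = TRUE) {
  dims <- c(max(2L, round(volume[1] / voxel_size_xy)),
            max(2L, round(volume[2] / voxel_size_xy)),
            max(2L, round(volume[3] / voxel_size_z)))
  amp <- coords$amplitude %||% rep(BACKGROUND_MEAN * (PEAK_OVER_BACKGROUND - 1), nrow(coords))
  s <- nuclear_diameter / 4
  arr <- stamp_blobs_3d(array(BACKGROUND_MEAN, dims),
                        coords$x_um / voxel_size_xy + 0.5,
                        coords$y_um / voxel_size_xy + 0.5,
                        coords$z_um / voxel_size_z + 0.5,
                        amp, s / voxel_size_xy, 2 * s / voxel_size_z)
  if (noise) arr <- array(rpois(length(arr), arr), dims)
  new_section_image(list(nuclear_reporter = arr, dapi = arr),
                    pixel_size_xy = voxel_size_xy, pixel_size_z = voxel_size_z)
}
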