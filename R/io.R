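#' @name io
#' @title Reading and writing pipeline artifacts
#' @description
#' Sections and stacks travel as multi-page TIFF (one page per channel,
#' or per z-plane for single-channel stacks) with a YAML sidecar carrying
#' channel names, physical pixel sizes and the intensity scale (the TIFF
#' writer stores [0,1] floats). Spots are CSV with a JSON parameter
#' sidecar; masks are single-channel 8-bit TIFF with the bit-exact
#' encoding 0 = outside, 1 = cortex, 2 = medulla; scenarios and
#' population specs are YAML.
NULL

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write / read a section image as TIFF plus metadata sidecar
#'
#' @param image a `section_image` (2D channels).
#' @param path output TIFF path; a `<path>.meta.yaml` sidecar is written
#'   alongside.
#' @export
write_section <- function(image, path) {
  chans <- image$channels
  scale <- max(unlist(lapply(chans, max)), 1)
  pages <- lapply(chans, function(m) {
    if (length(dim(m)) != 2) stop("write_section handles 2D channels only", call. = FALSE)
    t(m) / scale  # writeTIFF is row-major (y, x)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  yaml::write_yaml(list(
    channels = names(chans), pixel_size_xy = image$pixel_size_xy,
    pixel_size_z = if (is.na(image$pixel_size_z)) NULL else image$pixel_size_z,
    thickness = if (is.na(image$thickness)) NULL else image$thickness,
    intensity_scale = scale
  ), sidecar_path(path))
  invisible(path)
}

#' @rdname write_section
#' @param pixel_size pixel size in um, required when no sidecar exists.
#' @export
read_section <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_file <- sidecar_path(path)
  if (file.exists(meta_file)) {
    meta <- yaml::read_yaml(meta_file)
  } else {
    if (is.null(pixel_size)) {
      stop("no metadata sidecar found; supply pixel_size explicitly", call. = FALSE)
    }
    meta <- list(channels = paste0("channel", seq_along(pages)),
                 pixel_size_xy = pixel_size, intensity_scale = 1)
  }
  chans <- lapply(pages, function(p) t(p) * (meta$intensity_scale %||% 1))
  names(chans) <- meta$channels
  new_section_image(chans, pixel_size_xy = meta$pixel_size_xy,
                    pixel_size_z = meta$pixel_size_z %||% NA_real_,
                    thickness = meta$thickness %||% NA_real_)
}

#' Write / read a spot set as CSV plus JSON parameter sidecar
#'
#' @param spots a `spot_set`.
#' @param path output CSV path; parameters go to `<path>.params.json`.
#' @export
write_spots <- function(spots, path) {
  write.csv(spots$spots, path, row.names = FALSE)
  jsonlite::write_json(
    c(spots$params, list(undercount_risk = spots$undercount_risk)),
    paste0(path, ".params.json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  df <- read.csv(path)
  pfile <- paste0(path, ".params.json")
  params <- if (file.exists(pfile)) jsonlite::read_json(pfile, simplifyVector = TRUE) else list()
  risk <- isTRUE(params$undercount_risk)
  params$undercount_risk <- NULL
  new_spot_set(df, params, undercount_risk = risk)
}

#' Write / read a compartment mask as single-channel 8-bit TIFF
#'
#' Labels are stored bit-exactly (0 = outside, 1 = cortex, 2 = medulla) as
#' 8-bit samples; per-label areas go to a JSON sidecar.
#'
#' @param mask a `compartment_mask`.
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(t(mask$labels) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(list(
    pixel_size_xy = mask$pixel_size_xy, areas = as.list(mask$areas),
    single_compartment = mask$single_compartment
  ), paste0(path, ".areas.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @param pixel_size pixel size in um, required when no sidecar exists.
#' @export
read_mask <- function(path, pixel_size = NULL) {
  m <- tiff::readTIFF(path)
  labels <- matrix(as.integer(round(t(m) * 255)), ncol(m), nrow(m))
  afile <- paste0(path, ".areas.json")
  single <- FALSE
  if (file.exists(afile)) {
    meta <- jsonlite::read_json(afile, simplifyVector = TRUE)
    pixel_size <- meta$pixel_size_xy
    single <- isTRUE(meta$single_compartment)
  } else if (is.null(pixel_size)) {
    stop("no areas sidecar found; supply pixel_size explicitly", call. = FALSE)
  }
  new_compartment_mask(labels, pixel_size, single_compartment = single)
}

#' Write / read a tissue scenario as YAML
#'
#' @param scenario a `tissue_scenario`.
#' @param path YAML path.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  validate_scenario(structure(yaml::read_yaml(path), class = "tissue_scenario"))
}

#' Write / read flow event tables as CSV
#'
#' @param events a `flow_event_table`.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path)
  class(df) <- c("flow_event_table", "data.frame")
  df
}

#' Write ground truth centroids as CSV
#'
#' Columns `x_um`, `y_um` (, `z_um`), `population`, `compartment`.
#'
#' @param truth a `ground_truth`.
#' @param path CSV path.
#' @export
write_truth <- function(truth, path) {
  tec <- truth$tec
  thy <- truth$thymocytes
  tec$population <- "tec"
  thy$population <- "thymocyte"
  thy$reporter_positive <- NA
  cols <- intersect(c("x_um", "y_um", "z_um", "population", "compartment",
                      "reporter_positive"), names(tec))
  write.csv(rbind(tec[, cols], thy[, cols]), path, row.names = FALSE)
  invisible(path)
}
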