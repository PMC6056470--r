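#' @name morpho
#' @title Compartment morphometry, thymopoietic indices and stereology
#' @description
#' In-situ quantities derived from detected nuclei and compartment masks:
#' per-compartment TEC densities, the cortical-to-medullary TEC ratio, the
#' thymopoietic index (TI; thymocytes per TEC), whole-organ TI
#' reconstruction, stereological extrapolation of whole-organ TEC numbers
#' (Abercrombie correction), and the reconciliation of histological with
#' flow-cytometric measurements via the TI-based correction factor.
NULL

#' TEC density in one compartment
#'
#' Counts spots whose centroid pixel carries the compartment label and
#' divides by the compartment area; reported per 1e4 um^2
#' (density = count / area x 1e4, an exact identity).
#'
#' @param spots a `spot_set` or data frame with `x_um`, `y_um`.
#' @param mask a `compartment_mask` sharing the physical frame.
#' @param compartment `"cortex"` or `"medulla"`.
#' @return list of class `density_estimate`: `compartment`, `tec_count`,
#'   `area` (um^2), `density` (per 1e4 um^2).
#' @export
compartment_density <- function(spots, mask, compartment = c("cortex", "medulla")) {
  compartment <- match.arg(compartment)
  s <- if (inherits(spots, "spot_set")) spots$spots else spots
  area <- mask$areas[[compartment]]
  if (area <= 0) stop(sprintf("zero %s area in mask", compartment), call. = FALSE)
  code <- if (compartment == "cortex") COMP_CORTEX else COMP_MEDULLA
  lab <- map_label_at(mask$labels, s$x_um, s$y_um, mask$pixel_size_xy)
  n <- sum(lab == code)
  structure(list(compartment = compartment, tec_count = n, area = area,
                 density = n / area * 1e4),
            class = "density_estimate")
}

#' Cortical-to-medullary TEC ratio
#'
#' Ratio of compartment TEC totals per unit tissue:
#' (cortical density x cortex fraction) / (medullary density x medulla
#' fraction).
#'
#' @param cortex,medulla `density_estimate`s (or bare densities).
#' @param fractions an [area_fractions()] record (or a list with
#'   `cortex_fraction`, `medulla_fraction`).
#' @return list: `ratio` (Inf with `degenerate = TRUE` on a zero
#'   denominator), plus the weighted numerator/denominator.
#' @export
ctec_mtec_ratio <- function(cortex, medulla, fractions) {
  dc <- if (inherits(cortex, "density_estimate")) cortex$density else cortex
  dm <- if (inherits(medulla, "density_estimate")) medulla$density else medulla
  num <- dc * fractions$cortex_fraction
  den <- dm * fractions$medulla_fraction
  if (den <= 0) {
    return(list(ratio = Inf, cortical_weight = num, medullary_weight = den,
                degenerate = TRUE))
  }
  list(ratio = num / den, cortical_weight = num, medullary_weight = den,
       degenerate = FALSE)
}

#' Thymopoietic index
#'
#' TI = thymocytes / TECs. In the flow-cytometric formulation the index is
#' the inverse of the TEC fraction among events: `tec_fraction = 0.001`
#' gives TI = 1000. Exactly one of (`thymocyte_count`, `tec_count`) or
#' `tec_fraction` must be supplied.
#'
#' @param thymocyte_count,tec_count cell counts (`tec_count` must be > 0).
#' @param tec_fraction fraction of TECs among all cells, in (0, 1].
#' @param scope annotation: `"cortex"`, `"medulla"`, `"whole"` or `"flow"`.
#' @return list of class `ti_result`: `scope`, `thymocyte_count`,
#'   `tec_count`, `ti`.
#' @examples
#' thymopoietic_index(tec_fraction = 0.001)$ti  # 1000
#' thymopoietic_index(6100, 100)$ti             # 61
#' @export
thymopoietic_index <- function(thymocyte_count = NULL, tec_count = NULL,
                               tec_fraction = NULL, scope = "whole") {
  if (!is.null(tec_fraction)) {
    if (tec_fraction <= 0 || tec_fraction > 1) {
      stop("tec_fraction must lie in (0, 1]", call. = FALSE)
    }
    ti <- 1 / tec_fraction
    return(structure(list(scope = scope, thymocyte_count = NA_real_,
                          tec_count = NA_real_, ti = ti),
                     class = "ti_result"))
  }
  if (is.null(thymocyte_count) || is.null(tec_count)) {
    stop("supply thymocyte_count and tec_count, or tec_fraction", call. = FALSE)
  }
  if (tec_count <= 0) stop("tec_count must be > 0", call. = FALSE)
  if (thymocyte_count < 0) stop("thymocyte_count must be >= 0", call. = FALSE)
  structure(list(scope = scope, thymocyte_count = thymocyte_count,
                 tec_count = tec_count, ti = thymocyte_count / tec_count),
            class = "ti_result")
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf("<ti_result %s: TI = %.3g>\n", x$scope, x$ti))
  invisible(x)
}

#' Whole-organ thymopoietic index from compartment TIs
#'
#' Combines compartment TIs weighted by TEC numbers: with weights
#' proportional to per-compartment TEC counts, the weighted mean of TIs
#' equals total thymocytes / total TECs.
#'
#' @param cortex_ti,medulla_ti `ti_result`s or bare TI values.
#' @param tec_weights numeric length-2 (cortex, medulla), >= 0, sum > 0.
#' @return a `ti_result` with scope `"whole"`.
#' @export
whole_organ_ti <- function(cortex_ti, medulla_ti, tec_weights) {
  tc <- if (inherits(cortex_ti, "ti_result")) cortex_ti$ti else cortex_ti
  tm <- if (inherits(medulla_ti, "ti_result")) medulla_ti$ti else medulla_ti
  if (length(tec_weights) != 2 || any(tec_weights < 0) || sum(tec_weights) <= 0) {
    stop("tec_weights must be two non-negative numbers with positive sum",
         call. = FALSE)
  }
  w <- tec_weights / sum(tec_weights)
  ti <- w[1] * tc + w[2] * tm
  structure(list(scope = "whole",
                 thymocyte_count = w[1] * tc + w[2] * tm,
                 tec_count = 1, ti = ti),
            class = "ti_result")
}

#' Stereological whole-organ TEC totals
#'
#' Converts areal densities to volumetric ones with the Abercrombie
#' correction (effective thickness = section thickness + mean nuclear
#' diameter, compensating for nuclei counted in more than one notional
#' plane) and scales by compartment volumes derived from the area
#' fractions and the displacement-measured organ volume.
#'
#' @param cortex,medulla `density_estimate`s or densities per 1e4 um^2.
#' @param fractions an [area_fractions()] record.
#' @param scenario a `tissue_scenario` providing `organ_volume` (ul),
#'   `section_thickness` and `mean_nuclear_diameter` (um).
#' @param correction `"abercrombie"` or `"none"` (effective thickness =
#'   physical thickness; sensitivity mode).
#' @param effective_thickness optional explicit effective thickness in um,
#'   length 1 or 2 (cortex, medulla) to allow for the larger medullary
#'   nuclei.
#' @return list of class `stereology_result`: volumetric densities
#'   (per um^3), effective thickness, organ volume, per-compartment totals
#'   and `total_tec_estimate` (their sum).
#' @export
extrapolate_total_tecs <- function(cortex, medulla, fractions, scenario,
                                   correction = c("abercrombie", "none"),
                                   effective_thickness = NULL) {
  correction <- match.arg(correction)
  dc <- if (inherits(cortex, "density_estimate")) cortex$density else cortex
  dm <- if (inherits(medulla, "density_estimate")) medulla$density else medulla
  if (is.null(scenario$organ_volume) || !is.finite(scenario$organ_volume)) {
    stop("scenario must provide organ_volume (ul)", call. = FALSE)
  }
  if (is.null(effective_thickness)) {
    effective_thickness <- scenario$section_thickness +
      if (correction == "abercrombie") scenario$mean_nuclear_diameter else 0
  }
  eff <- rep(effective_thickness, length.out = 2)
  vol_um3 <- scenario$organ_volume * 1e9  # ul -> um^3
  vd_c <- dc / 1e4 / eff[1]
  vd_m <- dm / 1e4 / eff[2]
  tot_c <- vd_c * fractions$cortex_fraction * vol_um3
  tot_m <- vd_m * fractions$medulla_fraction * vol_um3
  structure(list(
    volumetric_density = c(cortex = vd_c, medulla = vd_m),
    effective_thickness = eff, organ_volume = scenario$organ_volume,
    compartment_totals = c(cortex = tot_c, medulla = tot_m),
    total_tec_estimate = tot_c + tot_m
  ), class = "stereology_result")
}

#' @export
print.stereology_result <- function(x, ...) {
  cat(sprintf("<stereology_result: %.2g TECs (cortex %.2g, medulla %.2g) at %.4g ul>\n",
              x$total_tec_estimate, x$compartment_totals[["cortex"]],
              x$compartment_totals[["medulla"]], x$organ_volume))
  invisible(x)
}

#' Reconcile histological and flow-cytometric TEC quantification
#'
#' The correction factor is the ratio of the flow-cytometric to the
#' histological thymopoietic index; multiplied onto the flow TEC count it
#' yields the dissociation-loss-corrected whole-organ TEC estimate. The
#' recovery rate is the flow count over the in-situ count when the latter
#' is available, else the TI ratio itself (valid when thymocyte recovery
#' is complete; the assumption is recorded in the report).
#'
#' @param ti_hist,ti_flow thymopoietic indices (> 0), `ti_result` or bare.
#' @param flow_tec_count TECs counted by flow cytometry.
#' @param insitu_tec_count optional in-situ (histology/light-sheet) count.
#' @return list of class `reconciliation_report`: `ti_hist`, `ti_flow`,
#'   `correction_factor`, `flow_tec_count`, `corrected_total`
#'   (= flow_tec_count x correction_factor, exact identity),
#'   `recovery_rate`, `recovery_basis`, `recovery_in_range`.
#' @examples
#' r <- reconcile(ti_hist = 61, ti_flow = 810, flow_tec_count = 1.12e5)
#' r$correction_factor  # ~13.3
#' @export
reconcile <- function(ti_hist, ti_flow, flow_tec_count,
                      insitu_tec_count = NULL) {
  th <- if (inherits(ti_hist, "ti_result")) ti_hist$ti else ti_hist
  tf <- if (inherits(ti_flow, "ti_result")) ti_flow$ti else ti_flow
  if (!is.finite(th) || th <= 0) stop("ti_hist must be > 0", call. = FALSE)
  if (!is.finite(tf) || tf <= 0) stop("ti_flow must be > 0", call. = FALSE)
  cf <- tf / th
  corrected <- flow_tec_count * cf
  if (!is.null(insitu_tec_count)) {
    recovery <- flow_tec_count / insitu_tec_count
    basis <- "insitu_count"
  } else {
    recovery <- th / tf
    basis <- "ti_ratio_assuming_equal_thymocyte_recovery"
  }
  structure(list(
    ti_hist = th, ti_flow = tf, correction_factor = cf,
    flow_tec_count = flow_tec_count, corrected_total = corrected,
    recovery_rate = recovery, recovery_basis = basis,
    recovery_in_range = recovery >= 0 && recovery <= 1
  ), class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat("<reconciliation_report>\n")
  cat(sprintf("  TI histology %.2g | TI flow %.2g | correction factor %.2g\n",
              x$ti_hist, x$ti_flow, x$correction_factor))
  cat(sprintf("  flow TECs %.3g -> corrected whole-organ total %.2g\n",
              x$flow_tec_count, x$corrected_total))
  cat(sprintf("  recovery rate %.2g (%s)%s\n", x$recovery_rate, x$recovery_basis,
              if (!x$recovery_in_range) " [OUT OF RANGE]" else ""))
  invisible(x)
}

#' Fold change between two ratios
#'
#' @param a,b positive quantities; returns `a / b`.
#' @export
fold_change <- function(a, b) {
  if (!is.finite(b) || b <= 0) stop("denominator must be > 0", call. = FALSE)
  a / b
}
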