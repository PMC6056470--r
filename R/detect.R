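#' @name detect
#' @title Nuclear spot detection
#' @description
#' Counts reporter-positive TEC nuclei in sections and stacks with a
#' multi-scale Laplacian-of-Gaussian blob detector: robust per-image
#' intensity normalization (1st to 99.9th percentile), scale-normalized
#' LoG responses at scales bracketing the expected nuclear diameter, local
#' maxima, a relative response threshold plus an absolute noise floor, and
#' greedy non-maximum suppression at half the expected diameter
#' (higher response wins; exact ties broken by coordinate order).
NULL

log_kernel_2d <- function(sigma_px) {
  r <- max(2L, ceiling(4 * sigma_px))
  g <- seq(-r, r)
  xx <- matrix(g, 2 * r + 1, 2 * r + 1)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  # negated scale-normalized LoG: positive response for bright blobs
  k <- -sigma_px^2 * ((r2 - 2 * sigma_px^2) / sigma_px^4) *
    exp(-r2 / (2 * sigma_px^2)) / (2 * pi * sigma_px^2)
  k - mean(k)  # zero-sum: no response to flat background
}

local_maxima_2d <- function(r) {
  nx <- nrow(r); ny <- ncol(r)
  m <- matrix(TRUE, nx, ny)
  pad <- function(di, dj) {
    s <- matrix(-Inf, nx, ny)
    si <- max(1, 1 + di):min(nx, nx + di)
    sj <- max(1, 1 + dj):min(ny, ny + dj)
    s[si, sj] <- r[si - di, sj - dj]
    s
  }
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    m <- m & (r >= pad(di, dj))
  }
  m[c(1, nx), ] <- FALSE
  m[, c(1, ny)] <- FALSE
  m
}

# quadratic sub-pixel refinement along one axis
subpixel_offset <- function(rm, r0, rp) {
  den <- rm - 2 * r0 + rp
  off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (rm - rp) / den, 0)
  pmin(pmax(off, -0.5), 0.5)
}

greedy_nms <- function(df, min_sep, dist_cols, z_scale = 1) {
  if (nrow(df) == 0) return(df)
  ord <- order(-df$response, df[[dist_cols[1]]], df[[dist_cols[2]]])
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  kept <- matrix(numeric(0), 0, length(dist_cols))
  for (i in seq_len(nrow(df))) {
    p <- as.numeric(df[i, dist_cols])
    if (length(dist_cols) == 3) p[3] <- p[3] / z_scale
    if (nrow(kept) > 0) {
      d2 <- rowSums((kept - matrix(p, nrow(kept), length(p), byrow = TRUE))^2)
      if (any(d2 < min_sep^2)) next
    }
    keep[i] <- TRUE
    kept <- rbind(kept, p)
  }
  df[keep, , drop = FALSE]
}

new_spot_set <- function(spots, params, undercount_risk = FALSE) {
  structure(list(spots = spots, params = params,
                 undercount_risk = undercount_risk),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set: %d spots%s>\n", nrow(x$spots),
              if (isTRUE(x$undercount_risk)) " [undercount risk]" else ""))
  invisible(x)
}

get_channel <- function(image, channel) {
  if (!inherits(image, "section_image")) stop("image must be a section_image", call. = FALSE)
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(image$channels), collapse = ", ")), call. = FALSE)
  }
  image$channels[[channel]]
}

#' Detect nuclear spots in a 2D section
#'
#' @param image a `section_image`.
#' @param channel channel name, default `"nuclear_reporter"`.
#' @param expected_diameter expected nuclear diameter in um (must exceed
#'   twice the pixel size to be resolvable).
#' @param threshold relative response threshold as a fraction of the
#'   maximum blob response in the image.
#' @param n_scales number of LoG scales bracketing the expected diameter.
#' @param abs_floor absolute response floor (normalized intensity units)
#'   below which maxima are treated as noise regardless of `threshold`.
#' @param noise_k multiple of the robust response spread (MAD) added to
#'   the floor; suppresses shot-noise maxima on blob-free images, where
#'   the percentile normalization stretches pure noise across the
#'   intensity range.
#' @param min_separation non-maximum-suppression radius in um; default
#'   `expected_diameter / 2`.
#' @return A `spot_set`: data frame of centroids (`x_um`, `y_um`),
#'   `intensity` (raw channel value at the peak), `response`, `sigma_um`;
#'   plus the detection parameters.
#' @examples
#' pts <- data.frame(x_um = c(20, 60), y_um = c(20, 40))
#' img <- render_points_section(pts, field_size = c(80, 80), noise = FALSE)
#' detect_spots_2d(img)$spots
#' @export
detect_spots_2d <- function(image, channel = "nuclear_reporter",
                            expected_diameter = 6, threshold = 0.2,
                            n_scales = 3, abs_floor = 0.1, noise_k = 6,
                            min_separation = expected_diameter / 2) {
  ch <- get_channel(image, channel)
  ps <- image$pixel_size_xy
  if (expected_diameter <= 2 * ps) {
    stop(sprintf(
      "expected_diameter %.3g um is below the resolvability limit 2 x pixel size (%.3g um)",
      expected_diameter, 2 * ps
    ), call. = FALSE)
  }
  norm <- robust_normalize(ch)
  x <- norm$x
  sig0 <- expected_diameter / 4 / ps
  sigmas <- sig0 * seq(0.8, 1.25, length.out = n_scales)
  cand <- list()
  for (s in sigmas) {
    resp <- EBImage::filter2(x, log_kernel_2d(s))
    resp <- matrix(as.numeric(resp), nrow(x), ncol(x))
    floor_s <- max(abs_floor, noise_k * stats::mad(resp))
    mx <- local_maxima_2d(resp)
    idx <- which(mx & resp > floor_s, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    i <- idx[, 1]; j <- idx[, 2]
    dx <- subpixel_offset(resp[cbind(i - 1L, j)], resp[cbind(i, j)], resp[cbind(i + 1L, j)])
    dy <- subpixel_offset(resp[cbind(i, j - 1L)], resp[cbind(i, j)], resp[cbind(i, j + 1L)])
    cand[[length(cand) + 1L]] <- data.frame(
      x_um = (i - 0.5 + dx) * ps, y_um = (j - 0.5 + dy) * ps,
      response = resp[cbind(i, j)], sigma_um = s * ps,
      intensity = ch[cbind(i, j)]
    )
  }
  params <- list(channel = channel, expected_diameter = expected_diameter,
                 threshold = threshold, n_scales = n_scales,
                 abs_floor = abs_floor, min_separation = min_separation)
  if (length(cand) == 0) {
    return(new_spot_set(data.frame(x_um = numeric(0), y_um = numeric(0),
                                   response = numeric(0), sigma_um = numeric(0),
                                   intensity = numeric(0)), params))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand$response >= threshold * max(cand$response), , drop = FALSE]
  spots <- greedy_nms(cand, min_separation, c("x_um", "y_um"))
  rownames(spots) <- NULL
  new_spot_set(spots, params)
}

local_maxima_3d <- function(r) {
  d <- dim(r)
  m <- array(TRUE, d)
  pad <- function(di, dj, dk) {
    s <- array(-Inf, d)
    si <- max(1, 1 + di):min(d[1], d[1] + di)
    sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
    sk <- max(1, 1 + dk):min(d[3], d[3] + dk)
    s[si, sj, sk] <- r[si - di, sj - dj, sk - dk]
    s
  }
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    m <- m & (r >= pad(di, dj, dk))
  }
  m[c(1, d[1]), , ] <- FALSE
  m[, c(1, d[2]), ] <- FALSE
  m[, , c(1, d[3])] <- FALSE
  m
}

laplacian_axis <- function(a, axis, spacing) {
  d <- dim(a)
  shift <- function(off) {
    s <- array(NA_real_, d)
    idx_src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    args <- list(a, seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    args[[axis + 1L]] <- idx_src
    do.call(`[`, args)
  }
  (shift(1L) + shift(-1L) - 2 * a) / spacing^2
}

#' Detect nuclear spots in an anisotropic 3D stack
#'
#' As [detect_spots_2d()] but volumetric, with the axial LoG scale widened
#' by `axial_sigma_ratio` to match the anisotropic axial blur of
#' light-sheet data. Also reports an `undercount_risk` flag, raised when
#' (a) detected nearest neighbours crowd axially below the axial
#' resolution (2 x axial blob sigma) at small lateral offset, or (b) a
#' spot's peak response is an outlier (> 1.7 x the median, with at least
#' 4 spots) consistent with two nuclei merged along z. The flag marks the
#' direction of bias (undercounting); it cannot recover merged nuclei.
#'
#' @inheritParams detect_spots_2d
#' @param stack a 3D `section_image` with known voxel sizes.
#' @param axial_sigma_ratio axial/lateral blur ratio of the imaging model.
#' @return A `spot_set` with `z_um` centroids and an `undercount_risk`
#'   logical.
#' @export
detect_spots_3d <- function(stack, channel = "nuclear_reporter",
                            expected_diameter = 6, threshold = 0.2,
                            n_scales = 3, abs_floor = 0.1, noise_k = 6,
                            min_separation = expected_diameter / 2,
                            axial_sigma_ratio = 2) {
  ch <- get_channel(stack, channel)
  if (length(dim(ch)) != 3) stop("stack channel must be 3D", call. = FALSE)
  ps <- stack$pixel_size_xy
  pz <- stack$pixel_size_z
  if (is.na(pz) || pz <= 0) stop("stack requires a positive pixel_size_z", call. = FALSE)
  if (expected_diameter <= 2 * ps) {
    stop("expected_diameter below resolvability limit (2 x pixel size)", call. = FALSE)
  }
  norm <- robust_normalize(ch)
  x <- norm$x
  sig0 <- expected_diameter / 4
  sigmas <- sig0 * seq(0.8, 1.25, length.out = n_scales)
  cand <- list()
  for (s in sigmas) {
    sz <- axial_sigma_ratio * s
    sm <- smooth3d(x, c(s / ps, s / ps, sz / pz))
    resp <- -(s^2 * (laplacian_axis(sm, 1, ps) + laplacian_axis(sm, 2, ps)) +
                sz^2 * laplacian_axis(sm, 3, pz))
    floor_s <- max(abs_floor, noise_k * stats::mad(resp))
    mx <- local_maxima_3d(resp)
    idx <- which(mx & resp > floor_s, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    cand[[length(cand) + 1L]] <- data.frame(
      x_um = (idx[, 1] - 0.5) * ps, y_um = (idx[, 2] - 0.5) * ps,
      z_um = (idx[, 3] - 0.5) * pz,
      response = resp[idx], sigma_um = s,
      intensity = ch[idx]
    )
  }
  params <- list(channel = channel, expected_diameter = expected_diameter,
                 threshold = threshold, n_scales = n_scales,
                 abs_floor = abs_floor, min_separation = min_separation,
                 axial_sigma_ratio = axial_sigma_ratio)
  if (length(cand) == 0) {
    return(new_spot_set(data.frame(x_um = numeric(0), y_um = numeric(0),
                                   z_um = numeric(0), response = numeric(0),
                                   sigma_um = numeric(0), intensity = numeric(0)),
                        params))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand$response >= threshold * max(cand$response), , drop = FALSE]
  spots <- greedy_nms(cand, min_separation, c("x_um", "y_um", "z_um"),
                      z_scale = axial_sigma_ratio)
  rownames(spots) <- NULL
  risk <- undercount_risk_flag(spots, expected_diameter, axial_sigma_ratio)
  new_spot_set(spots, params, undercount_risk = risk)
}

undercount_risk_flag <- function(spots, expected_diameter, axial_sigma_ratio) {
  n <- nrow(spots)
  if (n == 0) return(FALSE)
  axial_res <- 2 * axial_sigma_ratio * expected_diameter / 4
  crowded <- FALSE
  if (n >= 2) {
    nn_crowded <- 0L
    for (i in seq_len(n)) {
      dxy <- sqrt((spots$x_um - spots$x_um[i])^2 + (spots$y_um - spots$y_um[i])^2)
      dz <- abs(spots$z_um - spots$z_um[i])
      d <- sqrt(dxy^2 + dz^2)
      d[i] <- Inf
      j <- which.min(d)
      if (dz[j] < axial_res && dxy[j] < expected_diameter) nn_crowded <- nn_crowded + 1L
    }
    crowded <- nn_crowded / n > 0.1
  }
  bright_outlier <- n >= 4 && max(spots$response) > 1.7 * median(spots$response)
  crowded || bright_outlier
}

#' Score detected spots against ground truth
#'
#' One-to-one greedy matching by increasing distance within a match
#' radius; unmatched truth are false negatives, unmatched spots false
#' positives.
#'
#' @param spots a `spot_set` or data frame with `x_um`, `y_um` (, `z_um`).
#' @param truth a `ground_truth` (reporter-positive TEC nuclei are used)
#'   or a data frame of true centroids.
#' @param radius match radius in um.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#'   `precision` is `NA` when no spots were detected and `recall` is `NA`
#'   when the truth is empty.
#' @export
match_to_truth <- function(spots, truth, radius) {
  stopifnot(radius > 0)
  s <- if (inherits(spots, "spot_set")) spots$spots else spots
  t <- if (inherits(truth, "ground_truth")) {
    truth$tec[truth$tec$reporter_positive %||% rep(TRUE, nrow(truth$tec)), , drop = FALSE]
  } else truth
  ns <- nrow(s); nt <- nrow(t)
  if (ns == 0 || nt == 0) {
    return(list(tp = 0L, fp = ns, fn = nt,
                precision = if (ns == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                f1 = if (ns + nt == 0) NA_real_ else 0))
  }
  three_d <- !is.null(s$z_um) && !is.null(t$z_um)
  d2 <- outer(s$x_um, t$x_um, "-")^2 + outer(s$y_um, t$y_um, "-")^2
  if (three_d) d2 <- d2 + outer(s$z_um, t$z_um, "-")^2
  pairs <- which(d2 <= radius^2, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs) > 0) {
    ord <- order(d2[pairs])
    pairs <- pairs[ord, , drop = FALSE]
    used_s <- logical(ns); used_t <- logical(nt)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_s[i] && !used_t[j]) {
        used_s[i] <- TRUE; used_t[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- ns - tp
  fn <- nt - tp
  precision <- tp / ns
  recall <- tp / nt
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall, f1 = f1)
}
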