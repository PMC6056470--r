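#' @importFrom stats rpois rbinom rnorm runif quantile median pnorm setNames
#' @importFrom utils read.csv write.csv
NULL

# Multi-class Otsu: exhaustive search over 256-bin histograms for k-1
# thresholds maximizing between-class variance. EBImage::otsu is
# single-threshold; the two-threshold case is needed for
# outside/medulla/cortex splits, so both cases share this routine.
otsu_thresholds <- function(x, k = 2, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) return(rep(rng[1], k - 1))
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  if (k == 2) {
    # single threshold
    w0 <- cw
    m0 <- cm
    mt <- cm[levels]
    bcv <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
    bcv[!is.finite(bcv)] <- -Inf
    return(mids[which.max(bcv)])
  }
  if (k == 3) {
    mt <- cm[levels]
    best <- c(-Inf, 1L, 2L)
    for (i in seq_len(levels - 2L)) {
      w0 <- cw[i]; m0 <- cm[i]
      if (w0 <= 0) next
      j <- (i + 1L):(levels - 1L)
      w1 <- cw[j] - w0
      m1 <- cm[j] - m0
      w2 <- 1 - cw[j]
      m2 <- mt - cm[j]
      ok <- w1 > 0 & w2 > 0
      v <- rep(-Inf, length(j))
      v[ok] <- (m0^2 / w0 + m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok])
      jb <- which.max(v)
      if (v[jb] > best[1]) best <- c(v[jb], i, j[jb])
    }
    return(mids[best[2:3]])
  }
  stop("otsu_thresholds supports k = 2 or 3 classes")
}

# robust intensity normalization: 1st-99.9th percentile to [0, 1]
robust_normalize <- function(x, lo = 0.01, hi = 0.999) {
  q <- quantile(x, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(list(x = x * 0, scale = 1))
  list(x = (x - q[1]) / (q[2] - q[1]), scale = q[2] - q[1])
}

# separable Gaussian smoothing of a 3D array, physical sigma per axis (um),
# implemented as dense band-matrix products per dimension (BLAS-backed).
gauss_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k / sum(k)
}

conv_mat <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (d in seq_along(kernel)) {
    off <- d - r - 1L
    idx <- seq_len(n)
    src <- pmin(pmax(idx + off, 1L), n)  # replicate-pad borders
    m[cbind(idx, src)] <- m[cbind(idx, src)] + kernel[d]
  }
  m
}

smooth3d <- function(a, sigma_px) {
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma_px[ax] <= 0) next
    k <- gauss_kernel_1d(sigma_px[ax])
    m <- conv_mat(d[ax], k)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(a, perm)
    da <- dim(a)
    a <- m %*% matrix(a, nrow = da[1])
    dim(a) <- da
    a <- aperm(a, order(perm))
  }
  a
}

# seed substreams: fixed offsets per stage name so module-internal call
# order cannot perturb other stages' randomness
.substream_offsets <- c(
  imgen = 101L, detect = 211L, segment = 307L, morpho = 401L,
  cytosim = 503L, pipeline = 601L
)

substream_seed <- function(master_seed, stage, k = 0L) {
  off <- .substream_offsets[[stage]]
  (as.integer(master_seed) * 1000L + off + as.integer(k)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
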