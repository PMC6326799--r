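# Separable Gaussian smoothing of a 3D array (sigma in voxels per axis).
# Edge handling replicates border voxels. Used as a matched filter before
# local-maxima detection; the subvoxel fit runs on the raw image.
smooth_gauss <- function(arr, sigma = c(1, 1, 1)) {
  d <- dim(arr)
  for (a in 1:3) {
    if (sigma[a] <= 0) next
    rad <- max(1L, ceiling(3 * sigma[a]))
    k <- exp(-((-rad:rad)^2) / (2 * sigma[a]^2))
    k <- k / sum(k)
    acc <- array(0, dim = d)
    for (j in seq_along(k)) {
      off <- j - rad - 1L
      idx <- pmin(pmax(seq_len(d[a]) + off, 1L), d[a])
      acc <- acc + k[j] * switch(a,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE])
    }
    arr <- acc
  }
  arr
}

# Indices (n x 3) of 3D local maxima: strictly greater than half the
# 26-neighbourhood and >= the other half (lexicographic tie-break, so one
# maximum per plateau), restricted to voxels above `threshold`.
local_maxima_3d <- function(arr, threshold) {
  d <- dim(arr)
  cand <- array(arr > threshold, dim = d)
  shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dz == 0 & shifts$dy == 0 & shifts$dx == 0), ]
  shift_arr <- function(a, s) {
    idx1 <- pmin(pmax(seq_len(d[1]) + s[1], 1L), d[1])
    idx2 <- pmin(pmax(seq_len(d[2]) + s[2], 1L), d[2])
    idx3 <- pmin(pmax(seq_len(d[3]) + s[3], 1L), d[3])
    a[idx1, idx2, idx3, drop = FALSE]
  }
  for (r in seq_len(nrow(shifts))) {
    s <- as.integer(shifts[r, ])
    neigh <- shift_arr(arr, s)
    strict <- s[1] > 0 || (s[1] == 0 && (s[2] > 0 || (s[2] == 0 && s[3] > 0)))
    cand <- cand & (if (strict) arr > neigh else arr >= neigh)
    if (!any(cand)) break
  }
  which(cand, arr.ind = TRUE)
}

#' Detect diffraction-limited spots in a channel
#'
#' Local maxima above an adaptive robust threshold (median + k * MAD of
#' the channel, evaluated on a Gaussian-smoothed copy), merged within one
#' PSF and refined to sub-voxel position by least-squares fit of a 3D
#' Gaussian to the raw image patch around each maximum.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param k_mad threshold factor k (default 5).
#' @param psf_sigma expected PSF sigma (z, y, x) in um; sets the patch
#'   size, the merge radius and the fit initialisation.
#' @param merge_nsigma candidates closer than this many sigma (in
#'   PSF-normalised distance) are merged, keeping the brighter one.
#' @return data.frame(channel, z, y, x, peak_intensity, fitted_sigma);
#'   empty when nothing is detected.
#' @export
detect_spots <- function(stack, channel, k_mad = 5,
                         psf_sigma = c(0.4, 0.2, 0.2),
                         merge_nsigma = 2) {
  arr <- stack_channel(stack, channel)
  v <- stack$voxel_size
  sm <- smooth_gauss(arr, sigma = c(1, 1, 1))
  thr <- stats::median(sm) + k_mad * stats::mad(sm)
  peaks <- local_maxima_3d(sm, thr)
  empty <- data.frame(channel = character(), z = numeric(), y = numeric(),
                      x = numeric(), peak_intensity = numeric(),
                      fitted_sigma = numeric(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) return(empty)

  # merge duplicates within one PSF, brighter candidate wins
  ord <- order(arr[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  pos_um <- sweep(peaks - 0.5, 2L, v, "*")
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      later <- (i + 1L):nrow(peaks)
      dn <- sqrt(((pos_um[later, 1] - pos_um[i, 1]) / psf_sigma[1])^2 +
                 ((pos_um[later, 2] - pos_um[i, 2]) / psf_sigma[2])^2 +
                 ((pos_um[later, 3] - pos_um[i, 3]) / psf_sigma[3])^2)
      keep[later[dn < merge_nsigma]] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]

  fits <- lapply(seq_len(nrow(peaks)), function(i) {
    fit_spot_gaussian(arr, peaks[i, ], psf_sigma, v)
  })
  res <- do.call(rbind, fits)
  if (is.null(res)) return(empty)
  data.frame(channel = channel, z = res[, 1], y = res[, 2], x = res[, 3],
             peak_intensity = res[, 4], fitted_sigma = res[, 5],
             stringsAsFactors = FALSE)
}

# Least-squares 3D Gaussian fit around a voxel peak. Returns
# c(z, y, x, amplitude, sigma_scale) in um / counts.
fit_spot_gaussian <- function(arr, peak_idx, psf_sigma, voxel_size) {
  d <- dim(arr)
  rad <- pmax(2L, ceiling(2 * psf_sigma / voxel_size))
  rng <- lapply(1:3, function(a) {
    max(1L, peak_idx[a] - rad[a]):min(d[a], peak_idx[a] + rad[a])
  })
  patch <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  coords <- list((rng[[1]] - 0.5) * voxel_size[1],
                 (rng[[2]] - 0.5) * voxel_size[2],
                 (rng[[3]] - 0.5) * voxel_size[3])
  grid <- as.matrix(expand.grid(z = coords[[1]], y = coords[[2]],
                                x = coords[[3]]))
  vals <- as.vector(patch)  # expand.grid varies the first factor fastest,
                            # matching R's array linearisation (z fastest)
  bg0 <- min(vals)
  amp0 <- max(vals) - bg0
  w <- pmax(vals - bg0, 0)
  p0 <- if (sum(w) > 0) colSums(grid * w) / sum(w) else colMeans(grid)
  obj <- function(par) {
    mu <- par[1:3]
    amp <- exp(par[4])
    bg <- par[5]
    s <- exp(par[6])
    model <- bg + amp * exp(-0.5 * (((grid[, 1] - mu[1]) / (s * psf_sigma[1]))^2 +
                                    ((grid[, 2] - mu[2]) / (s * psf_sigma[2]))^2 +
                                    ((grid[, 3] - mu[3]) / (s * psf_sigma[3]))^2))
    sum((model - vals)^2)
  }
  fit <- stats::optim(c(p0, log(max(amp0, 1e-6)), bg0, 0), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  mu <- fit$par[1:3]
  # clamp to the patch: a fit escaping the patch falls back to the centroid
  for (a in 1:3) {
    if (mu[a] < min(coords[[a]]) || mu[a] > max(coords[[a]])) mu <- p0
  }
  c(mu, exp(fit$par[4]), exp(fit$par[6]) * mean(psf_sigma))
}
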