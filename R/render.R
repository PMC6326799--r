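#' Render a synthetic cell scene into an image stack
#'
#' Forward model for fluorescence acquisition. The DAPI channel is a
#' softened nucleus ellipsoid with a darkened nucleolus void; the pore-ring
#' channel is a shell peaked on the nuclear surface; the cytoplasmic-marker
#' channel fills the cell minus the nucleus. Each probe position renders as
#' a 3D Gaussian of the PSF sigma whose discrete sum equals
#' `photon_scale`, so the integrated above-background intensity of an
#' isolated spot is the photon budget. Poisson noise (default) is applied
#' to signal + background; `noise_model = "none"` gives the exact forward
#' model, under which the voxel argmax of an isolated spot is the voxel
#' containing its true position.
#'
#' @param scene a `cell_scene` from [generate_cell_scene()].
#' @param optics an [optics_params()].
#' @param seed integer seed for the noise draw.
#' @param dims stack dimensions (z, y, x) in voxels; default just covers
#'   the cell plus a margin.
#' @param channels channels to render; default DAPI, enabled markers and
#'   every probe colour present in the scene (probe channels are rendered
#'   with at least the three standard colours so that blank channels exist
#'   for negative controls).
#' @return An [image_stack()].
#' @export
render_image <- function(scene, optics = optics_params(), seed = NULL,
                         dims = NULL, channels = NULL) {
  g <- scene$geometry
  v <- optics$voxel_size
  if (is.null(dims)) {
    dims <- ceiling((g$cell_center + g$cell_radii + 0.3) / v)
  }
  dims <- as.integer(dims)
  ext <- dims * v
  if (any(g$cell_center + g$cell_radii > ext - 2 * v) ||
      any(g$cell_center - g$cell_radii < 2 * v)) {
    stop("scene exceeds stack bounds: enlarge dims or shrink the cell")
  }
  probe_channels <- union(c("red", "ir", "green"),
                          unique(scene$probes$channel))
  if (is.null(channels)) {
    channels <- c("dapi",
                  if (isTRUE(scene$markers[["pore"]])) "pore",
                  if (isTRUE(scene$markers[["cyto"]])) "cyto",
                  probe_channels)
  }

  zc <- (seq_len(dims[1]) - 0.5) * v[1]
  yc <- (seq_len(dims[2]) - 0.5) * v[2]
  xc <- (seq_len(dims[3]) - 0.5) * v[3]
  sq <- function(centers, center, radius) ((centers - center) / radius)^2
  grid_u <- function(center, radii) {
    sqrt(outer(outer(sq(zc, center[1], radii[1]),
                     sq(yc, center[2], radii[2]), "+"),
               sq(xc, center[3], radii[3]), "+"))
  }

  u_nuc <- NULL
  need_nuc <- any(c("dapi", "pore", "cyto") %in% channels)
  if (need_nuc) u_nuc <- grid_u(g$nucleus_center, g$nucleus_radii)

  out <- list()
  for (ch in channels) {
    arr <- array(optics$background_level, dim = dims)
    if (ch == "dapi") {
      q <- grid_u(g$nucleolus_center, rep(g$nucleolus_radius, 3L))
      void <- 1 - optics$nucleolus_depth * dapi_edge(q, 0.2)
      arr <- arr + optics$structure_scale *
        dapi_edge(u_nuc, optics$dapi_falloff) * void
    } else if (ch == "pore") {
      arr <- arr + optics$structure_scale *
        exp(-((u_nuc - 1)^2) / (2 * optics$pore_width^2))
    } else if (ch == "cyto") {
      u_cell <- grid_u(g$cell_center, g$cell_radii)
      arr <- arr + optics$structure_scale *
        dapi_edge(u_cell, 0.05) * (1 - dapi_edge(u_nuc, optics$dapi_falloff))
    }
    if (ch %in% probe_channels && nrow(scene$probes) > 0L) {
      rows <- which(scene$probes$channel == ch)
      for (r in rows) {
        pos <- c(scene$probes$z[r], scene$probes$y[r], scene$probes$x[r])
        arr <- add_spot(arr, pos, optics$psf_sigma, v, optics$photon_scale)
      }
    }
    out[[ch]] <- arr
  }

  out <- local_seed(seed, {
    lapply(out, function(arr) {
      if (optics$noise_model == "poisson") {
        array(stats::rpois(length(arr), arr), dim = dim(arr))
      } else if (optics$noise_model == "gaussian") {
        pmax(arr + stats::rnorm(length(arr), 0, optics$gaussian_sd), 0)
      } else arr
    })
  })
  image_stack(out, v)
}

# Add a separable 3D Gaussian at `pos` (um) with discrete sum = amplitude.
add_spot <- function(arr, pos, sigma, voxel_size, amplitude) {
  d <- dim(arr)
  axes <- vector("list", 3L)
  for (a in 1:3) {
    ci <- pos[a] / voxel_size[a] + 0.5
    rad <- max(2L, ceiling(4 * sigma[a] / voxel_size[a]))
    idx <- max(1L, floor(ci - rad)):min(d[a], ceiling(ci + rad))
    centers <- (idx - 0.5) * voxel_size[a]
    wts <- exp(-((centers - pos[a])^2) / (2 * sigma[a]^2))
    axes[[a]] <- list(idx = idx, w = wts)
  }
  kern <- outer(outer(axes[[1]]$w, axes[[2]]$w), axes[[3]]$w)
  kern <- kern / sum(kern) * amplitude
  arr[axes[[1]]$idx, axes[[2]]$idx, axes[[3]]$idx] <-
    arr[axes[[1]]$idx, axes[[2]]$idx, axes[[3]]$idx] + kern
  arr
}
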