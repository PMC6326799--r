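#' Multi-channel 3D image stack
#'
#' Container for a multi-channel voxel grid with a physical voxel size.
#' Voxel order is (z, y, x); the centre of voxel (i, j, k) sits at
#' ((i - 0.5) vz, (j - 0.5) vy, (k - 0.5) vx) um, i.e. the stack origin is
#' the outer corner of the first voxel.
#'
#' @param channels named list of 3D numeric arrays, all of identical
#'   dimension, non-negative intensities.
#' @param voxel_size voxel pitch (z, y, x) in um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))),
            length(voxel_size) == 3L, all(voxel_size > 0))
  d <- dim(channels[[1]])
  stopifnot(length(d) == 3L)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch), d)) {
      stop("channel '", nm, "' has inconsistent dimensions")
    }
    if (any(ch < 0)) stop("channel '", nm, "' has negative intensities")
  }
  structure(list(channels = channels,
                 voxel_size = as.numeric(voxel_size),
                 dim = d),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("image_stack:", paste(x$dim, collapse = " x "),
      "voxels (z y x),", length(x$channels), "channel(s):",
      paste(names(x$channels), collapse = ", "), "\n")
  cat("voxel size (um):", paste(x$voxel_size, collapse = " x "), "\n")
  invisible(x)
}

#' Physical extent of a stack
#' @param stack an `image_stack`.
#' @return length-3 numeric, extent in um along (z, y, x).
#' @export
stack_extent <- function(stack) stack$dim * stack$voxel_size

stack_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels)) {
    stop("channel '", channel, "' not present in stack (has: ",
         paste(names(stack$channels), collapse = ", "), ")")
  }
  stack$channels[[channel]]
}

# Trilinear interpolation of a 3D array at physical positions (n x 3, um).
# Positions are clamped to the voxel-centre lattice at the borders.
interp_trilinear <- function(arr, pos, voxel_size) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  d <- dim(arr)
  out <- numeric(nrow(pos))
  ci <- sweep(pos, 2L, voxel_size, "/") + 0.5       # continuous voxel index
  ci <- pmin(pmax(ci, 1), matrix(d, nrow(pos), 3L, byrow = TRUE))
  i0 <- floor(ci)
  i0 <- pmin(i0, matrix(d, nrow(pos), 3L, byrow = TRUE) - 1L)
  i0 <- pmax(i0, 1L)
  f <- ci - i0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dx) f[, 3] else 1 - f[, 3])
    idx <- cbind(pmin(i0[, 1] + dz, d[1]),
                 pmin(i0[, 2] + dy, d[2]),
                 pmin(i0[, 3] + dx, d[3]))
    out <- out + w * arr[idx]
  }
  out
}

#' Project a channel along z
#'
#' @param stack an `image_stack`.
#' @param channel channel name.
#' @param method `"max"` (default) or `"sum"`.
#' @return A 2D matrix (y, x).
#' @export
project_channel <- function(stack, channel, method = c("max", "sum")) {
  method <- match.arg(method)
  arr <- stack_channel(stack, channel)
  apply(arr, c(2L, 3L), if (method == "max") max else sum)
}

#' Select the focus plane of a channel by maximum variance
#'
#' Mirrors the classic maximum-variance focus criterion: the in-focus plane
#' of a z-stack is the one whose pixel intensities have the largest
#' variance. Ties resolve to the lowest plane index.
#'
#' @param stack an `image_stack`.
#' @param channel channel name (default `"dapi"`).
#' @return Integer plane index (1-based).
#' @export
find_focus_plane <- function(stack, channel = "dapi") {
  arr <- stack_channel(stack, channel)
  if (dim(arr)[1] < 1L) stop("stack has no z planes")
  v <- vapply(seq_len(dim(arr)[1]),
              function(i) stats::var(as.vector(arr[i, , ])), numeric(1))
  v[is.na(v)] <- 0
  which.max(v)  # which.max takes the first maximum: lowest-index tie rule
}

#' Write an image stack as multi-page TIFF files with a YAML sidecar
#'
#' One 32-bit float TIFF per channel (pages = z planes) plus
#' `<basename>.yaml` carrying the voxel size, channel names and the
#' per-channel intensity scale used to map counts into the unit interval.
#'
#' @param stack an `image_stack`.
#' @param basename path prefix; files are written as
#'   `<basename>_<channel>.tif` and `<basename>.yaml`.
#' @return Invisibly, the sidecar path.
#' @export
write_image_stack <- function(stack, basename) {
  meta <- list(voxel_size = as.numeric(stack$voxel_size),
               dim = as.integer(stack$dim),
               channels = list())
  for (nm in names(stack$channels)) {
    arr <- stack$channels[[nm]]
    scale <- max(arr, 1e-12)
    pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ] / scale)
    path <- paste0(basename, "_", nm, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    meta$channels[[nm]] <- list(file = base::basename(path), scale = scale)
  }
  sidecar <- paste0(basename, ".yaml")
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param basename the path prefix used when writing.
#' @return An `image_stack`.
#' @export
read_image_stack <- function(basename) {
  sidecar <- paste0(basename, ".yaml")
  if (!file.exists(sidecar)) stop("missing stack sidecar: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  dirn <- dirname(basename)
  channels <- list()
  for (nm in names(meta$channels)) {
    entry <- meta$channels[[nm]]
    path <- file.path(dirn, entry$file)
    if (!file.exists(path)) stop("missing channel file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(length(pages), dim(pages[[1]]))
    if (!identical(as.integer(d), as.integer(meta$dim))) {
      stop("TIFF '", path, "' does not match sidecar dimensions")
    }
    arr <- array(0, dim = d)
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * entry$scale
    channels[[nm]] <- arr
  }
  image_stack(channels, meta$voxel_size)
}
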