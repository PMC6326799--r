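#' Default cell geometry for the synthetic scene generator
#'
#' Dimensions approximate a fixed procyclic trypanosome: an ellipsoidal
#' cytoplasm, an ellipsoidal nucleus of roughly 2.5 um diameter and a
#' DAPI-dark spherical nucleolus at its centre. All lengths are in
#' micrometres, coordinate order is (z, y, x) with the stack origin at the
#' corner of voxel (1,1,1).
#'
#' @param cell_center,cell_radii centre and semi-axes of the cytoplasm
#'   ellipsoid (um).
#' @param nucleus_center,nucleus_radii centre and semi-axes of the nucleus
#'   ellipsoid (um).
#' @param nucleolus_center centre of the nucleolus; defaults to the nucleus
#'   centre.
#' @param nucleolus_radius radius of the spherical nucleolus (um).
#' @return A list of class `scene_geometry`.
#' @export
scene_geometry <- function(cell_center = c(2.0, 3.0, 3.0),
                           cell_radii = c(1.7, 2.6, 2.6),
                           nucleus_center = c(2.0, 3.0, 3.0),
                           nucleus_radii = c(1.0, 1.2, 1.2),
                           nucleolus_center = nucleus_center,
                           nucleolus_radius = 0.4) {
  g <- list(cell_center = cell_center, cell_radii = cell_radii,
            nucleus_center = nucleus_center, nucleus_radii = nucleus_radii,
            nucleolus_center = nucleolus_center,
            nucleolus_radius = nucleolus_radius)
  class(g) <- "scene_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(length(g$cell_center) == 3L, length(g$cell_radii) == 3L,
            length(g$nucleus_center) == 3L, length(g$nucleus_radii) == 3L,
            length(g$nucleolus_center) == 3L,
            length(g$nucleolus_radius) == 1L)
  if (any(g$cell_radii <= 0) || any(g$nucleus_radii <= 0) ||
      g$nucleolus_radius <= 0) {
    stop("all radii must be strictly positive")
  }
  # nucleolus strictly inside nucleus
  u <- ellipsoid_u(g$nucleolus_center, g$nucleus_center, g$nucleus_radii)
  if (u + g$nucleolus_radius / min(g$nucleus_radii) >= 1) {
    stop("infeasible geometry: nucleolus not strictly inside the nucleus")
  }
  # nucleus strictly inside cell (check along each axis from the centre)
  uc <- ellipsoid_u(g$nucleus_center, g$cell_center, g$cell_radii)
  if (uc + max(g$nucleus_radii / g$cell_radii) >= 1) {
    stop("infeasible geometry: nucleus not strictly inside the cell")
  }
  invisible(g)
}

#' Optical acquisition parameters for the image forward model
#'
#' @param voxel_size voxel pitch (z, y, x) in um.
#' @param psf_sigma Gaussian point-spread sigma (z, y, x) in um.
#' @param background_level constant camera background in counts (>= 0).
#' @param photon_scale integrated counts of one diffraction-limited spot.
#' @param noise_model `"poisson"` (default), `"gaussian"` or `"none"`.
#' @param gaussian_sd additive noise sd when `noise_model = "gaussian"`.
#' @param dapi_falloff edge softness of the nuclear DAPI signal, expressed in
#'   units of the normalised ellipsoid coordinate (dimensionless logistic
#'   width; smaller is sharper).
#' @param pore_width width of the pore-ring shell in the same units.
#' @param nucleolus_depth fractional DAPI darkening inside the nucleolus
#'   (0 = no void, 1 = fully dark).
#' @param structure_scale peak counts of the extended structures (DAPI,
#'   pore ring, cytoplasmic marker) above background.
#' @return A list of class `optics_params`.
#' @export
optics_params <- function(voxel_size = c(0.1, 0.1, 0.1),
                          psf_sigma = c(0.4, 0.2, 0.2),
                          background_level = 10,
                          photon_scale = 2e4,
                          noise_model = c("poisson", "gaussian", "none"),
                          gaussian_sd = 3,
                          dapi_falloff = 0.10,
                          pore_width = 0.08,
                          nucleolus_depth = 0.85,
                          structure_scale = 800) {
  noise_model <- match.arg(noise_model)
  o <- list(voxel_size = voxel_size, psf_sigma = psf_sigma,
            background_level = background_level, photon_scale = photon_scale,
            noise_model = noise_model, gaussian_sd = gaussian_sd,
            dapi_falloff = dapi_falloff, pore_width = pore_width,
            nucleolus_depth = nucleolus_depth,
            structure_scale = structure_scale)
  stopifnot(all(o$voxel_size > 0), all(o$psf_sigma > 0),
            o$background_level >= 0, o$photon_scale > 0,
            o$dapi_falloff > 0, o$pore_width > 0,
            o$nucleolus_depth >= 0, o$nucleolus_depth <= 1,
            o$structure_scale > 0, o$gaussian_sd > 0)
  class(o) <- "optics_params"
  o
}

# ---- analytic forward model -------------------------------------------------
# The DAPI edge is a logistic in the normalised nucleus coordinate u
# (u = 1 on the surface): s(u) = 1 / (1 + exp((u - 1) / w)). On the
# cytoplasmic flank of a profile the normalised %DAPI equals 100 * s(u), so
# percent and u are in closed-form correspondence. The generator places
# molecules through this inverse; the renderer evaluates the same model on
# the voxel grid.

dapi_edge <- function(u, falloff) 1 / (1 + exp((u - 1) / falloff))

percent_from_u <- function(u, falloff) 100 * dapi_edge(u, falloff)

u_from_percent <- function(percent, falloff) {
  stopifnot(all(percent > 0), all(percent < 100))
  1 + falloff * log(100 / percent - 1)
}

# In-plane nucleus coordinate of (y, x) positions relative to the central
# cross-section; equals min over z of the 3D u, hence governs max projections.
nucleus_u2d <- function(yx, geometry) {
  if (is.null(dim(yx))) yx <- matrix(yx, nrow = 1L)
  sqrt(((yx[, 1] - geometry$nucleus_center[2]) / geometry$nucleus_radii[2])^2 +
       ((yx[, 2] - geometry$nucleus_center[3]) / geometry$nucleus_radii[3])^2)
}

# Analytic %DAPI of (y, x) positions on a max projection of the model.
analytic_percent2d <- function(yx, geometry, optics) {
  percent_from_u(nucleus_u2d(yx, geometry), optics$dapi_falloff)
}
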