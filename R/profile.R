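#' Extract an intensity profile along a ray
#'
#' Samples one or more channels by linear interpolation at evenly spaced
#' arc positions along the segment from `start` (cytoplasmic end) to `end`
#' (nucleolar end). Positions are physical (z, y, x) in um. With a
#' projection mode the stack is first collapsed along z and sampling is
#' in-plane (the z components of `start`/`end` are ignored); with
#' `projection = "plane"` a single z plane (e.g. the focus plane) is used.
#'
#' @param stack an [image_stack()].
#' @param start,end length-3 positions (um) inside the stack.
#' @param step sampling step along the ray (um); default half the smallest
#'   voxel dimension.
#' @param channels channels to sample; default all.
#' @param projection `"none"` (3D sampling), `"max"`, `"sum"` or
#'   `"plane"`.
#' @param plane z plane index for `projection = "plane"`.
#' @return A `fish_profile`: list with `arc` (ordered distances, um),
#'   `positions`, `values` (named list of raw samples) and `normalized`
#'   (filled by [normalize_profile()]).
#' @export
extract_profile <- function(stack, start, end, step = NULL, channels = NULL,
                            projection = c("none", "max", "sum", "plane"),
                            plane = NULL) {
  projection <- match.arg(projection)
  channels <- channels %||% names(stack$channels)
  stopifnot(length(start) == 3L, length(end) == 3L)
  ext <- stack_extent(stack)
  step <- step %||% (min(stack$voxel_size) / 2)
  if (step <= 0) stop("sampling step must be positive")

  if (projection != "none") {
    # collapse to a single-plane stack; keep the physical (y, x) frame
    collapse <- function(arr) {
      m <- switch(projection,
        max = apply(arr, c(2L, 3L), max),
        sum = apply(arr, c(2L, 3L), sum),
        plane = {
          if (is.null(plane)) stop("projection = 'plane' needs `plane`")
          arr[plane, , ]
        })
      array(m, dim = c(1L, dim(arr)[2], dim(arr)[3]))
    }
    stack <- image_stack(lapply(stack$channels[channels], collapse),
                         stack$voxel_size)
    start[1] <- end[1] <- stack$voxel_size[1] / 2
    ext[1] <- stack$voxel_size[1]
  }
  if (any(start < 0) || any(start > ext) || any(end < 0) || any(end > ext)) {
    stop("profile endpoints must lie inside the stack")
  }
  len <- sqrt(sum((end - start)^2))
  if (len < step) stop("degenerate profile: start and end coincide")

  arc <- seq(0, len, by = step)
  tfrac <- arc / len
  pos <- cbind(start[1] + tfrac * (end[1] - start[1]),
               start[2] + tfrac * (end[2] - start[2]),
               start[3] + tfrac * (end[3] - start[3]))
  values <- lapply(channels, function(ch) {
    interp_trilinear(stack_channel(stack, ch), pos, stack$voxel_size)
  })
  names(values) <- channels
  structure(list(arc = arc, positions = pos, values = values,
                 normalized = NULL, step = step),
            class = "fish_profile")
}

#' Normalize profile channels to a 0-100% scale
#'
#' Affine rescale per channel with the profile minimum mapped to 0 and the
#' maximum to 100, the calibration underlying the %DAPI coordinate. The
#' result is invariant under positive affine transforms of the raw
#' intensities. By default the minimum is a robust one (1st percentile of
#' the samples, clamping below to 0) to damp single-sample noise.
#'
#' @param profile a `fish_profile`.
#' @param channels channels to normalize; default all sampled.
#' @param robust use the 1st percentile as the minimum (default TRUE);
#'   FALSE uses the exact minimum.
#' @return The profile with `$normalized` filled (values in `[0, 100]`,
#'   peak exactly 100).
#' @export
normalize_profile <- function(profile, channels = NULL, robust = TRUE) {
  channels <- channels %||% names(profile$values)
  norm <- profile$normalized %||% list()
  for (ch in channels) {
    v <- profile$values[[ch]]
    if (is.null(v)) stop("channel '", ch, "' not sampled in this profile")
    lo <- if (robust) stats::quantile(v, 0.01, names = FALSE) else min(v)
    hi <- max(v)
    if (hi <= lo) stop("channel '", ch, "' has no dynamic range on this profile")
    norm[[ch]] <- pmin(pmax((v - lo) / (hi - lo) * 100, 0), 100)
  }
  profile$normalized <- norm
  profile
}

profile_normalized <- function(profile, channel) {
  n <- profile$normalized[[channel]]
  if (is.null(n)) {
    profile <- normalize_profile(profile, channel)
    n <- profile$normalized[[channel]]
  }
  n
}

#' %DAPI coordinate of a position along a profile
#'
#' The %DAPI coordinate of a query is the normalized DAPI value at its arc
#' position, together with a side flag: queries before the DAPI peak (on
#' the path coming from the cytoplasm) are on the cytoplasmic flank,
#' queries beyond it on the nucleolar flank. All localization rules in
#' this package operate on the cytoplasmic flank.
#'
#' @param profile a `fish_profile` (DAPI normalized, or it will be).
#' @param query_arc arc position (um) within the profile support.
#' @param channel DAPI channel name.
#' @return A list of class `dapi_coordinate`: `percent` in `[0, 100]` and
#'   `side` (`"cytoplasmic"`, `"nucleolar"`, or `NA` at the peak).
#' @export
percent_dapi <- function(profile, query_arc, channel = "dapi") {
  arc <- profile$arc
  if (query_arc < arc[1] || query_arc > arc[length(arc)]) {
    stop("query arc position outside the profile support")
  }
  nv <- profile_normalized(profile, channel)
  pct <- stats::approx(arc, nv, xout = query_arc)$y
  peak_arc <- arc[which.max(nv)]  # lowest-index tie rule
  side <- if (abs(query_arc - peak_arc) < profile$step / 2) {
    NA_character_
  } else if (query_arc < peak_arc) "cytoplasmic" else "nucleolar"
  structure(list(percent = pct, side = side), class = "dapi_coordinate")
}

#' @export
print.dapi_coordinate <- function(x, ...) {
  cat(sprintf("%.1f %%DAPI (%s side)\n", x$percent,
              if (is.na(x$side)) "at peak" else x$side))
  invisible(x)
}

#' %DAPI position of a marker-channel maximum
#'
#' Locates the argmax of a marker channel (e.g. a nuclear-pore ring
#' protein) along the profile and reports the %DAPI coordinate there: the
#' border proxy used by the pore-marker calibration. Equal maxima resolve
#' to the one nearer the cytoplasmic end; a monotone marker channel (no
#' interior maximum) triggers a warning and returns the boundary value.
#'
#' @param profile a `fish_profile`.
#' @param marker_channel marker channel name.
#' @param dapi_channel DAPI channel name.
#' @param refine quadratic sub-sample refinement of the argmax (default
#'   TRUE): a parabola through the peak sample and its neighbours damps
#'   sampling aliasing of narrow ring profiles.
#' @return A `dapi_coordinate` with the extra field `arc` (um).
#' @export
marker_peak_position <- function(profile, marker_channel = "pore",
                                 dapi_channel = "dapi", refine = TRUE) {
  mv <- profile$values[[marker_channel]]
  if (is.null(mv)) stop("channel '", marker_channel, "' not sampled")
  idx <- which.max(mv)
  if (idx == 1L || idx == length(mv)) {
    warning("marker channel has no interior maximum; returning boundary value")
  }
  arc <- profile$arc[idx]
  if (refine && idx > 1L && idx < length(mv)) {
    denom <- mv[idx - 1L] - 2 * mv[idx] + mv[idx + 1L]
    if (denom < 0) {
      delta <- 0.5 * (mv[idx - 1L] - mv[idx + 1L]) / denom
      delta <- max(min(delta, 0.5), -0.5)
      arc <- arc + delta * profile$step
    }
  }
  co <- percent_dapi(profile, arc, channel = dapi_channel)
  co$arc <- arc
  co
}

#' %DAPI at the crossing of the marker and DAPI curves
#'
#' The cytoplasmic-marker calibration: both channels are normalized to
#' 0-100 on the profile, and the border proxy is the first arc position
#' (from the cytoplasmic end) where the normalized marker minus the
#' normalized DAPI changes sign, located by linear interpolation between
#' samples. Returns the DAPI percent at the crossing.
#'
#' @param profile a `fish_profile`.
#' @param dapi_channel,marker_channel channel names.
#' @param robust passed to [normalize_profile()].
#' @return A list with `percent` and `arc` (um).
#' @export
channel_intersection <- function(profile, dapi_channel = "dapi",
                                 marker_channel = "cyto", robust = TRUE) {
  profile <- normalize_profile(profile, c(dapi_channel, marker_channel),
                               robust = robust)
  dv <- profile$normalized[[dapi_channel]]
  mv <- profile$normalized[[marker_channel]]
  diff <- mv - dv
  n <- length(diff)
  cross <- which(diff[-n] * diff[-1] < 0)
  # an exact zero only counts as a crossing if the curves pass through each
  # other there (transversality); tangency or identity does not
  ii <- seq_along(diff)
  exact <- which(diff == 0 & ii > 1L & ii < n)
  exact <- exact[diff[pmax(exact - 1L, 1L)] * diff[pmin(exact + 1L, n)] < 0]
  if (length(exact)) cross <- sort(c(cross, exact))
  if (!length(cross)) stop("no transversal crossing of marker and DAPI curves")
  i <- cross[1]
  if (diff[i] == 0) {
    arc <- profile$arc[i]
    pct <- dv[i]
  } else {
    t <- diff[i] / (diff[i] - diff[i + 1])
    arc <- profile$arc[i] + t * (profile$arc[i + 1] - profile$arc[i])
    pct <- dv[i] + t * (dv[i + 1] - dv[i])
  }
  list(percent = pct, arc = arc)
}

#' Aggregate per-profile border proxies into a calibration
#'
#' @param profiles either a numeric vector of per-profile %DAPI values, or
#'   a list of `fish_profile` objects to evaluate with `method`.
#' @param method `"marker_peak"` or `"intersection"`.
#' @param marker_channel marker channel used by either method.
#' @param threshold reference threshold for the reported
#'   `fraction_below` (default 33.3, the single-signal cytoplasm rule).
#' @return A list of class `border_calibration`: `values`, `mean`, `sd`,
#'   `n`, `fraction_below_33`, `threshold`.
#' @export
calibrate_border <- function(profiles,
                             method = c("marker_peak", "intersection"),
                             marker_channel = NULL, threshold = 33.3) {
  method <- match.arg(method)
  if (is.numeric(profiles)) {
    values <- profiles[!is.na(profiles)]
  } else {
    marker_channel <- marker_channel %||%
      if (method == "marker_peak") "pore" else "cyto"
    values <- vapply(profiles, function(p) {
      res <- tryCatch(
        if (method == "marker_peak") {
          marker_peak_position(p, marker_channel = marker_channel)$percent
        } else {
          channel_intersection(p, marker_channel = marker_channel)$percent
        },
        error = function(e) NA_real_)
      res
    }, numeric(1))
    values <- values[!is.na(values)]
  }
  if (!length(values)) stop("no accepted profiles to calibrate from")
  structure(list(values = values,
                 mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else 0,
                 n = length(values),
                 fraction_below_33 = mean(values < threshold),
                 threshold = threshold,
                 method = method),
            class = "border_calibration")
}

#' @export
print.border_calibration <- function(x, ...) {
  cat(sprintf("border calibration (%s): %.1f +/- %.1f %%DAPI (n = %d), %.1f%% below %.1f%%\n",
              x$method, x$mean, x$sd, x$n, 100 * x$fraction_below_33,
              x$threshold))
  invisible(x)
}

# ---- per-spot measurement machinery ----------------------------------------

#' Intensity-weighted DAPI centroid
#'
#' Nucleus reference point for ray construction: voxels above 30% of the
#' channel maximum, intensity-weighted. Returns (z, y, x) um, or (y, x)
#' when `projection` collapses z.
#'
#' @param stack an [image_stack()].
#' @param channel DAPI channel name.
#' @param projection `"none"` or `"max"`.
#' @param level threshold as a fraction of the maximum.
#' @export
dapi_centroid <- function(stack, channel = "dapi", projection = "max",
                          level = 0.3) {
  if (projection == "max") {
    m <- project_channel(stack, channel, "max")
    w <- m * (m >= level * max(m))
    ys <- (seq_len(nrow(m)) - 0.5) * stack$voxel_size[2]
    xs <- (seq_len(ncol(m)) - 0.5) * stack$voxel_size[3]
    tot <- sum(w)
    c(sum(rowSums(w) * ys), sum(colSums(w) * xs)) / tot
  } else {
    arr <- stack_channel(stack, channel)
    w <- arr * (arr >= level * max(arr))
    d <- dim(arr)
    zs <- (seq_len(d[1]) - 0.5) * stack$voxel_size[1]
    ys <- (seq_len(d[2]) - 0.5) * stack$voxel_size[2]
    xs <- (seq_len(d[3]) - 0.5) * stack$voxel_size[3]
    tot <- sum(w)
    return(c(sum(apply(w, 1L, sum) * zs),
             sum(apply(w, 2L, sum) * ys),
             sum(apply(w, 3L, sum) * xs)) / tot)
  }
}

#' Nucleus mask on a z projection
#'
#' @param stack an [image_stack()].
#' @param channel DAPI channel.
#' @param level mask threshold as a fraction of the projected maximum;
#'   0.5 corresponds to the half-maximum DAPI edge.
#' @return Logical (y, x) matrix.
#' @export
nucleus_mask <- function(stack, channel = "dapi", level = 0.5) {
  m <- project_channel(stack, channel, "max")
  m >= level * max(m)
}

#' %DAPI coordinates of spot positions
#'
#' For each spot a measurement ray is constructed from the stack border
#' through the spot towards the DAPI-weighted nucleus centroid (the
#' cytoplasm-to-nucleolus direction of the coordinate system), the DAPI
#' profile along the ray is extracted on the z projection and normalized,
#' and the spot's %DAPI and side are read off at its arc position.
#'
#' @param stack an [image_stack()].
#' @param positions n x 3 matrix of spot positions (z, y, x) um, or a
#'   length-3 vector.
#' @param centroid optional (y, x) centroid override (um).
#' @param step profile sampling step (um).
#' @param dapi_channel DAPI channel name.
#' @param projection passed to [extract_profile()] (`"max"` default).
#' @return data.frame(percent, side, ok); `ok = FALSE` flags spots whose
#'   ray could not be constructed (outside the stack or at the centroid),
#'   to be excluded from tallies.
#' @export
spot_dapi_coordinates <- function(stack, positions, centroid = NULL,
                                  step = NULL, dapi_channel = "dapi",
                                  projection = "max") {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1L)
  step <- step %||% (min(stack$voxel_size) / 2)
  ext <- stack_extent(stack)
  if (is.null(centroid)) {
    cen3 <- dapi_centroid(stack, dapi_channel, projection = "none")
    centroid <- cen3[2:3]
  }
  margin <- 1.5 * max(stack$voxel_size[2:3])
  out <- data.frame(percent = rep(NA_real_, nrow(positions)),
                    side = NA_character_, ok = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(positions))) {
    spot <- positions[i, 2:3]
    dir <- spot - centroid
    len <- sqrt(sum(dir^2))
    if (len < 1e-6) next  # spot at the centroid: no ray direction
    dir <- dir / len
    # furthest t with centroid + t * dir inside [margin, ext - margin]
    tmax <- Inf
    for (a in 1:2) {
      if (dir[a] > 1e-12) {
        tmax <- min(tmax, (ext[a + 1] - margin - centroid[a]) / dir[a])
      } else if (dir[a] < -1e-12) {
        tmax <- min(tmax, (margin - centroid[a]) / dir[a])
      }
    }
    if (!is.finite(tmax) || tmax <= len) next  # spot beyond usable ray
    start <- c(0, centroid + tmax * dir)
    end <- c(0, centroid)
    prof <- extract_profile(stack, start, end, step = step,
                            channels = dapi_channel, projection = projection)
    prof <- normalize_profile(prof, dapi_channel)
    co <- tryCatch(percent_dapi(prof, tmax - len, channel = dapi_channel),
                   error = function(e) NULL)
    if (is.null(co)) next
    out$percent[i] <- co$percent
    out$side[i] <- co$side
    out$ok[i] <- TRUE
  }
  out
}

#' Four-ray border profiles of a nucleus
#'
#' Builds the per-nucleus profile set used for border calibration: rays at
#' four orthogonal in-plane angles from outside the nucleus towards the
#' DAPI centroid. For ring markers the profile is taken on the focus
#' plane; otherwise on the z projection.
#'
#' @param stack an [image_stack()].
#' @param channels channels to sample.
#' @param n_rays number of equally spaced rays (default 4).
#' @param mode `"plane"` (focus plane, for ring markers) or `"max"`.
#' @param step sampling step (um).
#' @return A list of `fish_profile` objects.
#' @export
border_profiles <- function(stack, channels = c("dapi", "pore"),
                            n_rays = 4L, mode = c("plane", "max"),
                            step = NULL) {
  mode <- match.arg(mode)
  step <- step %||% (min(stack$voxel_size) / 2)
  ext <- stack_extent(stack)
  cen3 <- dapi_centroid(stack, "dapi", projection = "none")
  centroid <- cen3[2:3]
  plane <- if (mode == "plane") find_focus_plane(stack, "dapi") else NULL
  margin <- 1.5 * max(stack$voxel_size[2:3])
  angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[seq_len(n_rays)]
  lapply(angles, function(a) {
    dir <- c(cos(a), sin(a))
    tmax <- Inf
    for (ax in 1:2) {
      if (dir[ax] > 1e-12) {
        tmax <- min(tmax, (ext[ax + 1] - margin - centroid[ax]) / dir[ax])
      } else if (dir[ax] < -1e-12) {
        tmax <- min(tmax, (margin - centroid[ax]) / dir[ax])
      }
    }
    start <- c(0, centroid + tmax * dir)
    end <- c(0, centroid)
    prof <- extract_profile(stack, start, end, step = step,
                            channels = channels,
                            projection = if (mode == "plane") "plane" else "max",
                            plane = plane)
    normalize_profile(prof, "dapi")
  })
}
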