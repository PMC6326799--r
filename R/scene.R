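#' @name molecule-vocabulary
#' @title Molecule species and localization vocabulary
#' @description
#' Species follow the three-colour probe layout: an mRNA carries a 5' probe
#' (red), an internal probe (infrared, "ir") and a 3' probe (green). An
#' intact molecule shows all three colours, a 5' part red + ir, a 3' part
#' ir + green; combinations spanning two gene ids indicate read-through
#' transcripts; an isolated signal is a single probe. Localization is
#' nucleus, nuclear periphery or cytoplasm.
#' @keywords internal
NULL

SPECIES_LEVELS <- c("intact", "five_prime_part", "three_prime_part",
                    "readthrough", "single_probe")
LOCATION_LEVELS <- c("nucleus", "nuclear_periphery", "cytoplasm")

#' Probe maps: channel to (gene, segment) assignments
#'
#' `probe_map_single_gene()` is the intramolecular three-colour layout
#' (5', internal and 3' probe on one gene). `probe_map_two_genes()` probes
#' across a gene border: red and ir on gene A, green on the 5' end of the
#' downstream gene B, so molecules carrying green together with an A probe
#' are read-through transcripts.
#'
#' @return data.frame with columns channel, gene, segment.
#' @export
probe_map_single_gene <- function() {
  data.frame(channel = c("red", "ir", "green"),
             gene = "geneA",
             segment = c("five_prime", "internal", "three_prime"),
             stringsAsFactors = FALSE)
}

#' @rdname probe_map_single_gene
#' @export
probe_map_two_genes <- function() {
  data.frame(channel = c("red", "ir", "green"),
             gene = c("geneA", "geneA", "geneB"),
             segment = c("five_prime", "internal", "five_prime"),
             stringsAsFactors = FALSE)
}

# Channels a ground-truth molecule of a given species carries under a map.
species_channels <- function(species, probe_map) {
  segs <- function(want) probe_map$channel[probe_map$segment %in% want &
                                           probe_map$gene == probe_map$gene[1]]
  switch(species,
    intact = segs(c("five_prime", "internal", "three_prime")),
    five_prime_part = segs(c("five_prime", "internal")),
    three_prime_part = segs(c("internal", "three_prime")),
    readthrough = probe_map$channel,
    single_probe = segs("five_prime"),
    stop("unknown species: ", species))
}

#' Specify molecule counts per species and location
#'
#' @param ... named integers `species.location = n`, e.g.
#'   `intact.cytoplasm = 5`, or a single data.frame with columns
#'   species, location, n.
#' @return data.frame(species, location, n).
#' @export
molecule_counts <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.data.frame(args[[1]])) {
    df <- args[[1]]
    stopifnot(all(c("species", "location", "n") %in% names(df)))
  } else if (length(args) == 0L) {
    return(data.frame(species = character(), location = character(),
                      n = integer(), stringsAsFactors = FALSE))
  } else {
    nm <- names(args)
    stopifnot(!is.null(nm), all(nzchar(nm)))
    parts <- strsplit(nm, ".", fixed = TRUE)
    df <- data.frame(
      species = vapply(parts, `[`, "", 1L),
      location = vapply(parts, `[`, "", 2L),
      n = vapply(args, function(x) as.integer(x), integer(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(df$species %in% SPECIES_LEVELS),
            all(df$location %in% LOCATION_LEVELS),
            all(df$n >= 0))
  df
}

empty_scene_tables <- function() {
  list(molecules = data.frame(molecule = integer(), species = character(),
                              location = character(),
                              oriented_5prime_out = logical(),
                              stringsAsFactors = FALSE),
       probes = data.frame(molecule = integer(), channel = character(),
                           z = numeric(), y = numeric(), x = numeric(),
                           stringsAsFactors = FALSE))
}

#' Generate a ground-truthed synthetic cell scene
#'
#' Places the requested number of molecules per (species, location) cell
#' inside an ellipsoidal cell/nucleus geometry. Placement uses the analytic
#' DAPI edge model, so every molecule's true localization class agrees with
#' the %DAPI band classification that the measurement side applies:
#' cytoplasmic molecules have all probes below 10 %DAPI, nuclear molecules
#' all probes above the periphery band, and periphery molecules straddle
#' the nuclear surface with at least one probe inside the 10-66.6% band
#' (and within one PSF sigma of the surface). For periphery molecules that
#' carry both the 5' and the internal probe, `orientation_fraction` of the
#' molecules are built with the 5' probe radially outside the internal
#' probe (the expected 5'-first export orientation); the rest are built
#' inverted.
#'
#' @param counts data.frame from [molecule_counts()].
#' @param orientation_fraction fraction of eligible periphery molecules
#'   built 5'-out, in `[0, 1]`. Default 0.81, the experimental scenario
#'   used throughout.
#' @param geometry a [scene_geometry()].
#' @param optics an [optics_params()] (the PSF defines the periphery
#'   ground-truth band and placement margins).
#' @param probe_map probe layout, see [probe_map_single_gene()].
#' @param compaction maximum pairwise distance between probes of one
#'   molecule (um); default 0.5, the observed compaction of single mRNAs.
#' @param min_separation minimum distance between probe positions of
#'   different molecules (um); keep above the pairing radius (plus a
#'   margin) when the scene will be rendered and re-detected, so that
#'   spot grouping cannot bridge molecules.
#' @param resolve_sigma minimum PSF-normalised distance between probe
#'   positions of different molecules in the same channel, so rendered
#'   same-colour spots stay optically resolvable; set 0 to disable for
#'   dense scenes that are consumed as ground truth without imaging.
#' @param seed integer seed; all randomness is local to this call.
#' @return A list of class `cell_scene` with elements `geometry`,
#'   `molecules` (one row per molecule), `probes` (one row per probe
#'   position, um) and `markers`.
#' @export
generate_cell_scene <- function(counts = molecule_counts(),
                                orientation_fraction = 0.81,
                                geometry = scene_geometry(),
                                optics = optics_params(),
                                probe_map = probe_map_single_gene(),
                                compaction = 0.5,
                                min_separation = 0.7,
                                resolve_sigma = 3,
                                seed = NULL) {
  stopifnot(orientation_fraction >= 0, orientation_fraction <= 1,
            compaction > 0, min_separation >= 0)
  validate_geometry(geometry)
  counts <- molecule_counts(counts)
  if ("readthrough" %in% counts$species[counts$n > 0] &&
      length(unique(probe_map$gene)) < 2L) {
    stop("readthrough molecules require a two-gene probe map")
  }

  local_seed(seed, {
    # place the most constrained compartment first: the periphery ring has
    # the least room, the cytoplasm the most
    counts <- counts[order(match(counts$location,
                                 c("nuclear_periphery", "nucleus",
                                   "cytoplasm"))), , drop = FALSE]

    # rejection sampling can paint itself into a corner (early molecules
    # blockading the space); restart the whole placement deterministically
    # from the seeded stream rather than failing on one unlucky layout
    tabs <- NULL
    for (attempt in seq_len(25L)) {
      tabs <- try(place_scene(counts, orientation_fraction, geometry, optics,
                              probe_map, compaction, min_separation,
                              resolve_sigma),
                  silent = TRUE)
      if (!inherits(tabs, "try-error")) break
    }
    if (inherits(tabs, "try-error")) stop(attr(tabs, "condition"))

    scene <- structure(list(geometry = geometry,
                            molecules = tabs$molecules,
                            probes = tabs$probes,
                            markers = c(pore = TRUE, cyto = TRUE),
                            probe_map = probe_map,
                            compaction = compaction,
                            orientation_fraction = orientation_fraction),
                       class = "cell_scene")
    validate_scene(scene)
    scene
  })
}

# -- placement helpers --------------------------------------------------------

# One complete placement pass over the expanded molecule list; consumes the
# current RNG stream and throws when a molecule cannot be placed, so the
# caller can restart. Orientation flags are independent
# Bernoulli(orientation_fraction) draws.
place_scene <- function(counts, orientation_fraction, geometry, optics,
                        probe_map, compaction, min_separation,
                        resolve_sigma) {
  tabs <- empty_scene_tables()
  placed_probes <- matrix(numeric(0), ncol = 3L)
  placed_channels <- character(0)
  mol_id <- 0L
  for (r in seq_len(nrow(counts))) {
    n <- counts$n[r]
    if (n == 0L) next
    species <- counts$species[r]
    location <- counts$location[r]
    chs <- species_channels(species, probe_map)
    has_pair <- all(c("red", "ir") %in% chs)
    oriented <- rep(NA, n)
    if (location == "nuclear_periphery" && has_pair) {
      oriented <- stats::runif(n) < orientation_fraction
    }
    for (i in seq_len(n)) {
      placed <- NULL
      for (try in seq_len(500L)) {
        cand <- place_molecule(species, location, oriented[i], chs,
                               geometry, optics, compaction)
        if (is.null(cand)) next
        if (nrow(placed_probes) > 0L) {
          pm <- do.call(rbind, cand$probes)
          ok_sep <- TRUE
          for (k in seq_len(nrow(pm))) {
            delta <- sweep(placed_probes, 2L, pm[k, ])
            if (min(row_norm(delta)) < min_separation) { ok_sep <- FALSE; break }
            # same-channel spots must also be optically resolvable
            same <- resolve_sigma > 0 & placed_channels == names(cand$probes)[k]
            if (any(same)) {
              dn <- sqrt((delta[same, 1] / optics$psf_sigma[1])^2 +
                         (delta[same, 2] / optics$psf_sigma[2])^2 +
                         (delta[same, 3] / optics$psf_sigma[3])^2)
              if (min(dn) < resolve_sigma) { ok_sep <- FALSE; break }
            }
          }
          if (!ok_sep) next
        }
        placed <- cand
        break
      }
      if (is.null(placed)) {
        stop("could not place a ", species, "/", location,
             " molecule after 500 tries; scene too crowded for ",
             "min_separation = ", min_separation)
      }
      mol_id <- mol_id + 1L
      placed_probes <- rbind(placed_probes, do.call(rbind, placed$probes))
      placed_channels <- c(placed_channels, names(placed$probes))
      tabs$molecules <- rbind(tabs$molecules, data.frame(
        molecule = mol_id, species = species, location = location,
        oriented_5prime_out = oriented[i], stringsAsFactors = FALSE))
      tabs$probes <- rbind(tabs$probes, data.frame(
        molecule = mol_id, channel = names(placed$probes),
        z = vapply(placed$probes, `[`, 0, 1L),
        y = vapply(placed$probes, `[`, 0, 2L),
        x = vapply(placed$probes, `[`, 0, 3L),
        row.names = NULL, stringsAsFactors = FALSE))
    }
  }
  tabs
}

# Placement margins in %DAPI: classes are generated strictly inside their
# bands so that interpolation error and photon noise on the measurement side
# cannot flip a class.
PLACE_CYTO_MAX <- 8       # all probes of a cytoplasmic molecule below this
PLACE_NUC_MIN <- 70       # all probes of a nuclear molecule above this
PLACE_BAND <- c(20, 50)   # anchor band for periphery probes
PLACE_IN <- c(75, 88)     # inner (nuclear-side) probe of oriented pairs

max_pairwise <- function(pm) {
  if (nrow(pm) < 2L) return(0)
  max(stats::dist(pm))
}

runif_ball <- function(radius) {
  repeat {
    v <- stats::runif(3L, -radius, radius)
    if (sum(v * v) <= radius^2) return(v)
  }
}

inside_cell <- function(pos, g, margin = 0.95) {
  all(ellipsoid_u(pos, g$cell_center, g$cell_radii) <= margin)
}

# Point on the u-scaled nucleus cross-section ellipse at parameter angle
# theta, at height z.
point_at_u <- function(u, theta, z, g) {
  c(z,
    g$nucleus_center[2] + u * g$nucleus_radii[2] * cos(theta),
    g$nucleus_center[3] + u * g$nucleus_radii[3] * sin(theta))
}

# Returns list(anchor, probes = named list of positions) or NULL on failure.
place_molecule <- function(species, location, oriented, chs,
                           g, optics, compaction) {
  w <- optics$dapi_falloff
  pct <- function(pos) {
    if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
    analytic_percent2d(pos[, 2:3, drop = FALSE], g, optics)
  }

  if (location == "nuclear_periphery") {
    theta <- stats::runif(1L, 0, 2 * pi)
    z <- g$nucleus_center[1] + stats::runif(1L, -0.15, 0.15)
    for (try in seq_len(200L)) {
      probes <- list()
      if (all(c("red", "ir") %in% chs) && !is.na(oriented)) {
        p_out <- stats::runif(1L, PLACE_BAND[1], PLACE_BAND[2])
        p_in <- stats::runif(1L, PLACE_IN[1], PLACE_IN[2])
        u_red <- u_from_percent(if (oriented) p_out else p_in, w)
        u_ir <- u_from_percent(if (oriented) p_in else p_out, w)
        probes$red <- point_at_u(u_red, theta, z + stats::runif(1, -0.03, 0.03), g)
        probes$ir <- point_at_u(u_ir, theta, z + stats::runif(1, -0.03, 0.03), g)
        for (ch in setdiff(chs, c("red", "ir"))) {
          probes[[ch]] <- probes$ir + runif_ball(0.10)
        }
      } else {
        p0 <- stats::runif(1L, PLACE_BAND[1], PLACE_BAND[2])
        anchor <- point_at_u(u_from_percent(p0, w), theta, z, g)
        probes[[chs[1]]] <- anchor
        for (ch in chs[-1]) probes[[ch]] <- anchor + runif_ball(0.10)
      }
      pm <- do.call(rbind, probes)
      pcts <- pct(pm)
      ok <- any(pcts >= PLACE_BAND[1] - 5 & pcts <= PLACE_BAND[2] + 8) &&
        max_pairwise(pm) <= compaction &&
        inside_cell(pm, g)
      if (ok) return(list(anchor = colMeans(pm), probes = probes))
    }
    return(NULL)
  }

  if (location == "cytoplasm") {
    for (try in seq_len(500L)) {
      lo <- g$cell_center - g$cell_radii
      hi <- g$cell_center + g$cell_radii
      anchor <- stats::runif(3L, lo, hi)
      if (!inside_cell(anchor, g, 0.92)) next
      if (ellipsoid_u(anchor, g$nucleus_center, g$nucleus_radii) < 1.15) next
      if (pct(anchor) >= 2) next
      probes <- stats::setNames(
        lapply(chs, function(ch) anchor + runif_ball(0.12)), chs)
      pm <- do.call(rbind, probes)
      if (all(pct(pm) < PLACE_CYTO_MAX) &&
          all(ellipsoid_u(pm, g$nucleus_center, g$nucleus_radii) > 1.05) &&
          max_pairwise(pm) <= compaction && inside_cell(pm, g)) {
        return(list(anchor = anchor, probes = probes))
      }
    }
    return(NULL)
  }

  # nucleus
  for (try in seq_len(500L)) {
    lo <- g$nucleus_center - g$nucleus_radii
    hi <- g$nucleus_center + g$nucleus_radii
    anchor <- stats::runif(3L, lo, hi)
    if (ellipsoid_u(anchor, g$nucleus_center, g$nucleus_radii) > 0.75) next
    if (row_norm(matrix(anchor - g$nucleolus_center, 1L)) <
        1.3 * g$nucleolus_radius) next
    probes <- stats::setNames(
      lapply(chs, function(ch) anchor + runif_ball(0.10)), chs)
    pm <- do.call(rbind, probes)
    if (all(pct(pm) > PLACE_NUC_MIN) &&
        all(ellipsoid_u(pm, g$nucleus_center, g$nucleus_radii) < 0.95) &&
        all(row_norm(sweep(pm, 2L, g$nucleolus_center)) >
            1.1 * g$nucleolus_radius) &&
        max_pairwise(pm) <= compaction) {
      return(list(anchor = anchor, probes = probes))
    }
  }
  NULL
}

validate_scene <- function(scene) {
  g <- scene$geometry
  validate_geometry(g)
  if (nrow(scene$probes) > 0L) {
    pm <- as.matrix(scene$probes[, c("z", "y", "x")])
    if (any(ellipsoid_u(pm, g$cell_center, g$cell_radii) >= 1)) {
      stop("scene invariant violated: probe position outside the cell")
    }
    for (m in unique(scene$probes$molecule)) {
      sub <- pm[scene$probes$molecule == m, , drop = FALSE]
      if (nrow(sub) > 1L && max(stats::dist(sub)) > scene$compaction + 1e-9) {
        stop("scene invariant violated: molecule ", m,
             " exceeds the compaction distance")
      }
    }
  }
  invisible(scene)
}

#' @export
print.cell_scene <- function(x, ...) {
  cat("cell_scene with", nrow(x$molecules), "molecules,",
      nrow(x$probes), "probe positions\n")
  if (nrow(x$molecules)) print(table(x$molecules$species, x$molecules$location))
  invisible(x)
}

#' Write / read the ground truth tables of a scene
#'
#' Molecules and probe positions are stored as two TSV files,
#' `<basename>_molecules.tsv` and `<basename>_probes.tsv`.
#'
#' @param scene a `cell_scene`.
#' @param basename path prefix.
#' @return Invisibly, the molecule-table path.
#' @export
write_scene_truth <- function(scene, basename) {
  utils::write.table(scene$molecules, paste0(basename, "_molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scene$probes, paste0(basename, "_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(basename, "_molecules.tsv"))
}
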