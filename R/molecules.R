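#' Group detected spots into molecules
#'
#' Links spots across colour channels into molecules by repeated merging
#' of mutually nearest clusters: at every step the closest admissible pair
#' of clusters is merged, where a pair is admissible when the two clusters
#' share no channel and every pairwise spot distance in the merged cluster
#' is at most `pairing_radius` (complete linkage, so a molecule can never
#' extend beyond the cap). The globally closest admissible pair is always
#' a mutual nearest-neighbour pair, and the result is independent of input
#' order. Spots left unlinked become `single_probe` molecules.
#'
#' @param spots data.frame with columns channel, z, y, x (um) as returned
#'   by [detect_spots()] (rows from several channels concatenated).
#' @param pairing_radius maximum pairwise spot distance within one
#'   molecule (um); default 0.5, the observed mRNA compaction limit.
#' @return The input data.frame with a `molecule` integer column added;
#'   molecule ids are numbered in order of their first spot after
#'   canonical (channel, z, y, x) sorting.
#' @export
group_spots_to_molecules <- function(spots, pairing_radius = 0.5) {
  stopifnot(all(c("channel", "z", "y", "x") %in% names(spots)))
  n <- nrow(spots)
  if (n == 0L) {
    spots$molecule <- integer(0)
    return(spots)
  }
  ord <- order(spots$channel, spots$z, spots$y, spots$x)
  P <- as.matrix(spots[ord, c("z", "y", "x")])
  chan <- spots$channel[ord]
  D <- as.matrix(stats::dist(P))
  cluster <- seq_len(n)

  repeat {
    best <- NULL
    best_d <- Inf
    ids <- unique(cluster)
    for (ii in seq_along(ids)) {
      for (jj in seq_len(ii - 1L)) {
        a <- which(cluster == ids[ii])
        b <- which(cluster == ids[jj])
        if (length(intersect(chan[a], chan[b]))) next
        link <- max(D[a, b])
        if (link <= pairing_radius && link < best_d - 1e-12) {
          best_d <- link
          best <- c(ids[ii], ids[jj])
        }
      }
    }
    if (is.null(best)) break
    cluster[cluster == max(best)] <- min(best)
  }

  ids <- unique(cluster)  # in first-appearance order of the canonical sort
  remap <- stats::setNames(seq_along(ids), ids)
  mol_sorted <- as.integer(remap[as.character(cluster)])
  spots$molecule <- NA_integer_
  spots$molecule[ord] <- mol_sorted
  spots
}

#' Classify the species of a molecule from its channel set
#'
#' Applies the colour-combination rules of three-colour intramolecular
#' FISH: channels covering the 5', internal and 3' segment of one gene are
#' an intact molecule; 5' + internal a 5' part; internal + 3' a 3' part;
#' any combination spanning two gene ids a read-through transcript; a
#' lone channel a single probe. Other single-gene combinations are not
#' defined by the probe layout and return `NA`.
#'
#' @param channels character vector of channel names present in the
#'   molecule.
#' @param probe_map data.frame(channel, gene, segment), see
#'   [probe_map_single_gene()].
#' @return One of the species labels, or `NA_character_`.
#' @export
classify_molecule_species <- function(channels, probe_map) {
  m <- match(channels, probe_map$channel)
  if (anyNA(m)) {
    stop("channel(s) not covered by the probe map: ",
         paste(channels[is.na(m)], collapse = ", "))
  }
  genes <- probe_map$gene[m]
  segs <- sort(probe_map$segment[m])
  if (length(channels) == 1L) return("single_probe")
  if (length(unique(genes)) >= 2L) return("readthrough")
  if (identical(segs, sort(c("five_prime", "internal", "three_prime")))) {
    return("intact")
  }
  if (identical(segs, sort(c("five_prime", "internal")))) {
    return("five_prime_part")
  }
  if (identical(segs, sort(c("internal", "three_prime")))) {
    return("three_prime_part")
  }
  NA_character_
}

#' Localization class from a molecule's %DAPI coordinates
#'
#' The band rule applied to the %DAPI coordinates of one molecule's
#' spots: nuclear periphery if any spot lies inside the band on the
#' cytoplasmic flank (edges inclusive), cytoplasm if every spot is below
#' `cyto_cut` on the cytoplasmic flank, otherwise nucleus. Spots on the
#' nucleolar flank or at the peak can never vote for cytoplasm or
#' periphery.
#'
#' @param percent numeric %DAPI values of the molecule's spots.
#' @param side flank of each spot (`"cytoplasmic"`, `"nucleolar"` or
#'   `NA` at the peak).
#' @param band periphery band, default `c(10, 66.6)`.
#' @param cyto_cut cytoplasm threshold, default 10.
#' @return `"nuclear_periphery"`, `"cytoplasm"` or `"nucleus"`.
#' @export
classify_location <- function(percent, side, band = c(10, 66.6),
                              cyto_cut = 10) {
  stopifnot(length(percent) == length(side), length(percent) >= 1L)
  cyto_side <- !is.na(side) & side == "cytoplasmic"
  in_band <- cyto_side & percent >= band[1] & percent <= band[2]
  if (any(in_band)) return("nuclear_periphery")
  if (all(cyto_side & percent < cyto_cut)) return("cytoplasm")
  "nucleus"
}

#' Build the per-molecule table from grouped spots
#'
#' Adds species labels and %DAPI coordinates, then classifies each
#' molecule's localization with the periphery band rule: a molecule with
#' at least one FISH signal between `band[1]` and `band[2]` %DAPI
#' (cytoplasmic flank, edges inclusive) is at the nuclear periphery; a
#' molecule with all signals below `cyto_cut` on the cytoplasmic flank is
#' cytoplasmic; everything else (including signals on the nucleolar
#' flank) is nuclear. Molecules containing a spot whose measurement ray
#' fails are flagged unclassifiable (`location = NA`) and excluded from
#' tallies.
#'
#' @param spots grouped spots from [group_spots_to_molecules()].
#' @param stack the [image_stack()] the spots came from (for DAPI rays).
#' @param probe_map probe layout.
#' @param band periphery band in %DAPI, default `c(10, 66.6)`.
#' @param cyto_cut cytoplasm threshold in %DAPI, default 10.
#' @param centroid optional (y, x) nucleus centroid override.
#' @return list with `molecules` (molecule, species, location, channels)
#'   and `spots` (input plus percent, side, ok).
#' @export
localize_molecules <- function(spots, stack, probe_map = probe_map_single_gene(),
                               band = c(10, 66.6), cyto_cut = 10,
                               centroid = NULL) {
  stopifnot("molecule" %in% names(spots))
  coords <- spot_dapi_coordinates(stack, as.matrix(spots[, c("z", "y", "x")]),
                                  centroid = centroid)
  spots$percent <- coords$percent
  spots$side <- coords$side
  spots$ok <- coords$ok

  mols <- lapply(split(seq_len(nrow(spots)), spots$molecule), function(idx) {
    sub <- spots[idx, ]
    species <- classify_molecule_species(sub$channel, probe_map)
    loc <- if (any(!sub$ok)) {
      NA_character_
    } else {
      classify_location(sub$percent, sub$side, band, cyto_cut)
    }
    data.frame(molecule = sub$molecule[1], species = species, location = loc,
               channels = paste(sort(sub$channel), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  molecules <- do.call(rbind, c(mols, list(make.row.names = FALSE)))
  molecules <- molecules[order(molecules$molecule), , drop = FALSE]
  list(molecules = molecules, spots = spots)
}

#' Export-orientation analysis of 5' vs internal signals
#'
#' Implements the 5'-first export statistic: among molecules that carry
#' both the 5' and the internal probe and whose connecting segment
#' intersects the nucleus (mask test on the z projection), count those
#' whose 5' signal sits at a lower %DAPI than the internal signal, i.e.
#' further towards the cytoplasm — the orientation expected if the 5' end
#' leads nuclear export.
#'
#' @param spots localized spots (the `spots` element of
#'   [localize_molecules()]; needs percent and ok columns).
#' @param stack the [image_stack()] (for the nucleus mask).
#' @param probe_map probe layout; the 5' and internal channels are taken
#'   from the gene carrying the internal probe.
#' @param mask optional logical nucleus mask (y, x) overriding
#'   [nucleus_mask()].
#' @param n_samples points sampled along each connecting segment for the
#'   mask-intersection test.
#' @return list of class `orientation_result`: `n_eligible`,
#'   `n_five_prime_first`, `fraction` (`NA` when nothing is eligible),
#'   `n_excluded` and `records` (per-molecule %DAPI of both signals).
#' @export
orientation_analysis <- function(spots, stack,
                                 probe_map = probe_map_single_gene(),
                                 mask = NULL, n_samples = 100L) {
  if (is.null(mask)) mask <- nucleus_mask(stack)
  int_row <- probe_map[probe_map$segment == "internal", ][1, ]
  five_ch <- probe_map$channel[probe_map$segment == "five_prime" &
                               probe_map$gene == int_row$gene][1]
  int_ch <- int_row$channel
  if (is.na(five_ch) || is.na(int_ch)) {
    stop("probe map does not define a 5' and an internal channel on one gene")
  }
  v <- stack$voxel_size
  records <- list()
  n_excluded <- 0L
  for (m in unique(spots$molecule)) {
    sub <- spots[spots$molecule == m, ]
    if (!all(c(five_ch, int_ch) %in% sub$channel)) next
    s5 <- sub[sub$channel == five_ch, ][1, ]
    si <- sub[sub$channel == int_ch, ][1, ]
    if (!isTRUE(s5$ok) || !isTRUE(si$ok)) next
    tt <- seq(0, 1, length.out = n_samples)
    ys <- s5$y + tt * (si$y - s5$y)
    xs <- s5$x + tt * (si$x - s5$x)
    iy <- pmin(pmax(ceiling(ys / v[2]), 1L), nrow(mask))
    ix <- pmin(pmax(ceiling(xs / v[3]), 1L), ncol(mask))
    if (!any(mask[cbind(iy, ix)])) {
      n_excluded <- n_excluded + 1L
      next
    }
    records[[length(records) + 1L]] <- data.frame(
      molecule = m, percent_5prime = s5$percent, percent_internal = si$percent,
      five_prime_first = s5$percent < si$percent, stringsAsFactors = FALSE)
  }
  records <- if (length(records)) {
    do.call(rbind, c(records, list(make.row.names = FALSE)))
  } else {
    data.frame(molecule = integer(), percent_5prime = numeric(),
               percent_internal = numeric(), five_prime_first = logical())
  }
  n_eligible <- nrow(records)
  n_first <- sum(records$five_prime_first)
  structure(list(n_eligible = n_eligible,
                 n_five_prime_first = n_first,
                 fraction = if (n_eligible > 0L) n_first / n_eligible else NA_real_,
                 n_excluded = n_excluded,
                 records = records),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("orientation: %d/%d molecules 5'-first (%.1f%%), %d excluded\n",
              x$n_five_prime_first, x$n_eligible,
              100 * (x$fraction %||% NA), x$n_excluded))
  invisible(x)
}

#' Tally molecules by species and location, per cell
#'
#' @param molecules data.frame with columns species, location and
#'   optionally `cell` (one scene = one cell in synthetic mode; a missing
#'   cell column means a single cell). Molecules with `NA` location
#'   (unclassifiable) are excluded and counted separately.
#' @return list with `counts` (species x location totals over all cells),
#'   `per_cell` (mean and sd of per-cell counts for each species x
#'   location combination) and `n_unclassifiable`.
#' @export
per_cell_counts <- function(molecules) {
  if (!"cell" %in% names(molecules)) molecules$cell <- rep(1L, nrow(molecules))
  bad <- is.na(molecules$location) | is.na(molecules$species)
  n_uncl <- sum(bad)
  molecules <- molecules[!bad, , drop = FALSE]
  cells <- unique(molecules$cell)
  grid <- expand.grid(species = SPECIES_LEVELS, location = LOCATION_LEVELS,
                      stringsAsFactors = FALSE)
  count_cell <- function(df) {
    vapply(seq_len(nrow(grid)), function(i) {
      sum(df$species == grid$species[i] & df$location == grid$location[i])
    }, numeric(1))
  }
  per <- vapply(cells, function(cl) {
    count_cell(molecules[molecules$cell == cl, , drop = FALSE])
  }, numeric(nrow(grid)))
  per <- matrix(per, nrow = nrow(grid))
  counts <- cbind(grid, n = rowSums(per))
  per_cell <- cbind(grid,
                    mean = rowMeans(per),
                    sd = apply(per, 1L, function(r) {
                      if (length(r) > 1L) stats::sd(r) else 0
                    }))
  list(counts = counts, per_cell = per_cell, n_unclassifiable = n_uncl,
       n_cells = length(cells))
}

#' Theoretical extended contour length of an mRNA
#'
#' Single-stranded RNA has a contour length of about 0.34 nm per
#' nucleotide, so a fully extended transcript of `n_nt` nucleotides spans
#' `n_nt * 0.34 / 1000` um. For the 22,197-nt FUTSCH reporter this is the
#' ~7.5 um theoretical maximum distance between its 5' and 3' probes,
#' against which the observed ~0.5 um compaction is compared.
#'
#' @param n_nt transcript length in nucleotides.
#' @param nm_per_nt contour length per nucleotide (nm), default 0.34.
#' @return Length in um.
#' @export
mrna_contour_length <- function(n_nt, nm_per_nt = 0.34) {
  stopifnot(n_nt > 0, nm_per_nt > 0)
  n_nt * nm_per_nt / 1000
}
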