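# Shared fixtures: everything is generated in code at test time.

quick_counts <- function() {
  molecule_counts(intact.nucleus = 3, intact.cytoplasm = 4,
                  five_prime_part.nuclear_periphery = 4,
                  three_prime_part.cytoplasm = 3)
}

expected_count_matrix <- function() {
  want <- matrix(0, 5, 3, dimnames = list(
    c("intact", "five_prime_part", "three_prime_part", "readthrough",
      "single_probe"),
    c("nucleus", "nuclear_periphery", "cytoplasm")))
  want["intact", "nucleus"] <- 3
  want["intact", "cytoplasm"] <- 4
  want["five_prime_part", "nuclear_periphery"] <- 4
  want["three_prime_part", "cytoplasm"] <- 3
  want
}

count_matrix_from <- function(molecules) {
  tab <- table(factor(molecules$species, levels = rownames(expected_count_matrix())),
               factor(molecules$location, levels = colnames(expected_count_matrix())))
  matrix(tab, nrow = 5, dimnames = dimnames(expected_count_matrix()))
}

# Jittered per-scene geometry, as nuclei vary between cells.
jittered_geometry <- function() {
  scene_geometry(nucleus_radii = c(1.0, 1.2, 1.2) * stats::runif(3, 0.92, 1.08),
                 nucleus_center = c(2, 3, 3) + stats::runif(3, -0.08, 0.08))
}

# Detect + group + localize one rendered stack with defaults.
quantify_stack <- function(stack) {
  spots <- do.call(rbind, lapply(c("red", "ir", "green"), function(ch) {
    detect_spots(stack, ch)
  }))
  spots <- group_spots_to_molecules(spots)
  localize_molecules(spots, stack)
}

# Ground-truth molecules of a scene as a localized spot table (no imaging),
# for orientation studies at scale.
truth_spots <- function(scene, stack) {
  spots <- data.frame(channel = scene$probes$channel, z = scene$probes$z,
                      y = scene$probes$y, x = scene$probes$x,
                      molecule = scene$probes$molecule,
                      stringsAsFactors = FALSE)
  co <- spot_dapi_coordinates(stack, as.matrix(spots[, c("z", "y", "x")]))
  spots$percent <- co$percent
  spots$side <- co$side
  spots$ok <- co$ok
  spots
}

# Brute-force grouping oracle: enumerate all channel-respecting partitions
# with complete linkage <= cap; prefer more linked pairs, then smaller total
# intra-molecule distance. Returns the set of optimal partitions (each a
# canonical string), so callers can skip instances with ties.
oracle_partitions <- function(spots, cap) {
  n <- nrow(spots)
  P <- as.matrix(spots[, c("z", "y", "x")])
  D <- as.matrix(stats::dist(P))
  chan <- spots$channel
  parts <- list(list())
  for (i in seq_len(n)) {
    nxt <- list()
    for (p in parts) {
      for (g in seq_along(p)) {
        grp <- p[[g]]
        if (chan[i] %in% chan[grp]) next
        if (any(D[i, grp] > cap)) next
        q <- p
        q[[g]] <- c(grp, i)
        nxt[[length(nxt) + 1L]] <- q
      }
      p[[length(p) + 1L]] <- i
      nxt[[length(nxt) + 1L]] <- p
    }
    parts <- nxt
  }
  score <- vapply(parts, function(p) {
    links <- sum(vapply(p, function(g) choose(length(g), 2L), numeric(1)))
    dist <- sum(vapply(p, function(g) {
      if (length(g) < 2L) 0 else sum(D[g, g][upper.tri(D[g, g])])
    }, numeric(1)))
    links * 1e6 - dist
  }, numeric(1))
  best <- which(score > max(score) - 1e-9)
  unique(vapply(parts[best], function(p) {
    paste(sort(vapply(p, function(g) paste(sort(g), collapse = "-"), "")),
          collapse = "|")
  }, ""))
}

partition_string <- function(molecule_ids) {
  paste(sort(vapply(split(seq_along(molecule_ids), molecule_ids),
                    function(g) paste(sort(g), collapse = "-"), "")),
        collapse = "|")
}
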