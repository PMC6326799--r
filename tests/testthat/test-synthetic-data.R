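test_that("empty counts give an empty scene and blank probe channels", {
  sc <- generate_cell_scene(molecule_counts(), seed = 1)
  expect_equal(nrow(sc$molecules), 0L)
  expect_equal(nrow(sc$probes), 0L)
  st <- render_image(sc, optics_params(noise_model = "none"))
  for (ch in c("red", "ir", "green")) {
    expect_true(all(st$channels[[ch]] == optics_params()$background_level))
  }
})

test_that("cytoplasmic molecules are placed outside the nucleus, nuclear ones inside", {
  sc <- generate_cell_scene(molecule_counts(intact.cytoplasm = 10),
                            seed = 2)
  g <- sc$geometry
  pm <- as.matrix(sc$probes[, c("z", "y", "x")])
  u <- periFISH:::ellipsoid_u(pm, g$nucleus_center, g$nucleus_radii)
  expect_true(all(u > 1))
  uc <- periFISH:::ellipsoid_u(pm, g$cell_center, g$cell_radii)
  expect_true(all(uc < 1))

  sc2 <- generate_cell_scene(molecule_counts(intact.nucleus = 6), seed = 3)
  pm2 <- as.matrix(sc2$probes[, c("z", "y", "x")])
  u2 <- periFISH:::ellipsoid_u(pm2, g$nucleus_center, g$nucleus_radii)
  expect_true(all(u2 < 1))
})

test_that("periphery molecules straddle the surface and honour the orientation fraction", {
  sc <- generate_cell_scene(
    molecule_counts(five_prime_part.nuclear_periphery = 100),
    orientation_fraction = 0.81, min_separation = 0.05,
    resolve_sigma = 0, seed = 4)
  g <- sc$geometry
  opt <- optics_params()
  # at least one probe of each molecule within one in-plane PSF sigma of
  # the surface (the geometric ground-truth definition of periphery)
  for (m in sc$molecules$molecule) {
    pm <- as.matrix(sc$probes[sc$probes$molecule == m, c("z", "y", "x")])
    u2 <- periFISH:::nucleus_u2d(pm[, 2:3, drop = FALSE], g)
    dist_surface <- abs(u2 - 1) * min(g$nucleus_radii[2:3])
    expect_true(any(dist_surface <= opt$psf_sigma[2] + 1e-9))
  }
  # orientation flags: Bernoulli(0.81) over n = 100
  n_or <- sum(sc$molecules$oriented_5prime_out)
  expect_gt(n_or, 100 * 0.81 - 3 * sqrt(100 * 0.81 * 0.19))
  expect_lt(n_or, 100 * 0.81 + 3 * sqrt(100 * 0.81 * 0.19))
  # the flag reflects the geometry: 5' (red) farther out than internal (ir)
  for (m in sc$molecules$molecule) {
    sub <- sc$probes[sc$probes$molecule == m, ]
    u_red <- periFISH:::nucleus_u2d(c(sub$y[sub$channel == "red"],
                                      sub$x[sub$channel == "red"]), g)
    u_ir <- periFISH:::nucleus_u2d(c(sub$y[sub$channel == "ir"],
                                     sub$x[sub$channel == "ir"]), g)
    expect_equal(u_red > u_ir,
                 sc$molecules$oriented_5prime_out[sc$molecules$molecule == m])
  }
})

test_that("scene invariants hold and infeasible geometry is rejected", {
  sc <- generate_cell_scene(quick_counts(), seed = 5)
  for (m in unique(sc$probes$molecule)) {
    pm <- as.matrix(sc$probes[sc$probes$molecule == m, c("z", "y", "x")])
    if (nrow(pm) > 1L) expect_lte(max(dist(pm)), sc$compaction + 1e-9)
  }
  expect_error(scene_geometry(nucleolus_radius = 1.5),
               "nucleolus not strictly inside")
  expect_error(scene_geometry(nucleus_radii = c(2, 3, 3)),
               "nucleus not strictly inside")
})

test_that("scenes, matrices and sequences are bit-identical under one seed", {
  a <- generate_cell_scene(quick_counts(), seed = 42)
  b <- generate_cell_scene(quick_counts(), seed = 42)
  expect_identical(a$probes, b$probes)
  expect_identical(a$molecules, b$molecules)
  la <- generate_lfq_dataset(lfq_ground_truth(), seed = 42)
  lb <- generate_lfq_dataset(lfq_ground_truth(), seed = 42)
  expect_identical(la$matrix$values, lb$matrix$values)
  sa <- generate_protein_sequences(5, 180, 1, seed = 42)
  sb <- generate_protein_sequences(5, 180, 1, seed = 42)
  expect_identical(as.character(sa$sequences), as.character(sb$sequences))
  # and the generator does not disturb the caller's RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(generate_cell_scene(quick_counts(), seed = 1))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a rendered isolated spot peaks at its true voxel and integrates to the photon budget", {
  sc <- generate_cell_scene(molecule_counts(single_probe.cytoplasm = 1),
                            seed = 6)
  opt <- optics_params(noise_model = "none")
  st <- render_image(sc, opt)
  arr <- st$channels$red - opt$background_level
  peak <- which(arr == max(arr), arr.ind = TRUE)[1, ]
  true_vox <- floor(c(sc$probes$z, sc$probes$y, sc$probes$x) /
                    opt$voxel_size) + 1
  expect_equal(unname(peak), unname(true_vox))
  expect_equal(sum(arr), opt$photon_scale, tolerance = 1e-6)
})

test_that("spot conservation: one rendered local maximum per ground-truth probe", {
  sc <- generate_cell_scene(quick_counts(), seed = 7)
  st <- render_image(sc, optics_params(noise_model = "none"))
  for (ch in c("red", "ir", "green")) {
    n_truth <- sum(sc$probes$channel == ch)
    expect_equal(nrow(detect_spots(st, ch)), n_truth)
  }
})

test_that("LFQ null construction is centred and missingness is abundance-dependent", {
  d <- generate_lfq_dataset(lfq_ground_truth(n_proteins = 400, n_enriched = 0,
                                             log2_effect_size = 0,
                                             missingness_steepness = 0,
                                             n_flagged = 0), seed = 8)
  v <- log2(d$matrix$values)
  diff <- rowMeans(v[, 4:6]) - rowMeans(v[, 1:3])
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(length(diff)))

  d2 <- generate_lfq_dataset(lfq_ground_truth(n_proteins = 600, n_flagged = 0),
                             seed = 9)
  base <- rowMeans(log2(d2$matrix$values), na.rm = TRUE)
  keep <- is.finite(base)  # fully missing rows have no observed abundance
  base <- base[keep]
  miss <- rowMeans(is.na(d2$matrix$values))[keep]
  dec <- cut(base, quantile(base, c(0, 0.1, 0.9, 1)), include.lowest = TRUE)
  miss_rate <- tapply(miss, dec, mean)
  expect_gt(miss_rate[1], miss_rate[3])
})

test_that("planted Q-rich windows are exact ground truth for the scanner", {
  sq <- generate_protein_sequences(12, lengths = c(300, 120, 61),
                                  planted = c(0, 2, 1), seed = 10)
  sc <- qrich_scan_set(sq$sequences)
  expect_equal(sc$n_qrich, sq$truth$n_planted)
  expect_equal(sc$density, sq$truth$n_planted / sq$truth$length * 100)
  expect_error(generate_protein_sequences(1, lengths = 50, planted = 1),
               "planted")
})
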