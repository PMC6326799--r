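# Build a small stack directly from arrays for deterministic profile tests.
toy_stack <- function(dapi_fun, nz = 5L, ny = 40L, nx = 40L, v = 0.1,
                      extra = list()) {
  grid_plane <- function(f) {
    Y <- rep((seq_len(ny) - 0.5) * v, times = nx)
    X <- rep((seq_len(nx) - 0.5) * v, each = ny)
    vals <- f(Y, X)
    if (length(vals) == 1L) vals <- rep(vals, length(Y))
    matrix(vals, ny, nx)
  }
  channels <- c(list(dapi = dapi_fun), extra)
  channels <- lapply(channels, function(f) {
    pl <- grid_plane(f)
    array(rep(pl, each = nz), dim = c(nz, ny, nx))
  })
  image_stack(channels, c(v, v, v))
}

test_that("focus plane is the maximum-variance plane, ties to the lowest index", {
  arr <- array(1, dim = c(10, 8, 8))
  arr[7, , ] <- matrix(runif(64), 8, 8)
  st <- image_stack(list(dapi = arr), c(0.1, 0.1, 0.1))
  expect_equal(find_focus_plane(st), 7L)
  flat <- image_stack(list(dapi = array(2, dim = c(6, 4, 4))), c(0.1, 0.1, 0.1))
  expect_equal(find_focus_plane(flat), 1L)
  # rendered nucleus centred mid-stack: brute-force variance per plane
  sc <- generate_cell_scene(molecule_counts(), seed = 1)
  stn <- render_image(sc, optics_params(noise_model = "none"))
  vars <- sapply(seq_len(stn$dim[1]), function(i) var(as.vector(stn$channels$dapi[i, , ])))
  expect_equal(find_focus_plane(stn), which.max(vars))
  expect_lt(abs(find_focus_plane(stn) - stn$dim[1] / 2), 3)
})

test_that("profile extraction interpolates along the ray and rejects bad input", {
  st <- toy_stack(function(y, x) 100 * y)  # linear ramp in y
  p <- extract_profile(st, c(0.25, 0.5, 2), c(0.25, 3.5, 2), step = 0.05)
  expect_true(all(diff(p$arc) > 0))
  # linear field: sampled values equal the field at sample positions
  expect_equal(p$values$dapi, 100 * p$positions[, 2], tolerance = 1e-8)
  expect_error(extract_profile(st, c(0.25, 1, 1), c(0.25, 1, 1)), "degenerate")
  expect_error(extract_profile(st, c(0.25, -5, 1), c(0.25, 1, 1)), "inside")
  cst <- toy_stack(function(y, x) 7)
  pc <- extract_profile(cst, c(0.25, 0.5, 2), c(0.25, 3.5, 2))
  expect_true(all(pc$values$dapi == 7))
})

test_that("a profile through a noise-free nucleus rises to one peak then falls to the nucleolus", {
  sc <- generate_cell_scene(molecule_counts(), seed = 2)
  st <- render_image(sc, optics_params(noise_model = "none"))
  p <- extract_profile(st, c(2.05, 3, 0.3), c(2.05, 3, 3), step = 0.05,
                       channels = "dapi")
  v <- p$values$dapi
  i <- which.max(v)
  expect_gt(i, 1L)
  expect_lt(i, length(v))
  expect_true(all(diff(v[1:i]) > -1e-6))        # monotone rise
  expect_lt(v[length(v)], 0.5 * max(v))          # nucleolar dip at the end
})

test_that("normalization is an affine 0-100 rescale, invariant and idempotent", {
  st <- toy_stack(function(y, x) 200 + 4800 * pmax(0, 1 - abs(y - 2)))
  p <- extract_profile(st, c(0.25, 0.3, 2), c(0.25, 2, 2), step = 0.05)
  p <- normalize_profile(p, "dapi", robust = FALSE)
  expect_equal(max(p$normalized$dapi), 100)
  expect_equal(min(p$normalized$dapi), 0)
  # doubling raw intensities changes nothing
  p2 <- p
  p2$values$dapi <- p$values$dapi * 2
  p2$normalized <- NULL
  p2 <- normalize_profile(p2, "dapi", robust = FALSE)
  expect_equal(p2$normalized$dapi, p$normalized$dapi)
  # idempotence: normalizing the normalized values is the identity
  p3 <- p
  p3$values$dapi <- p$normalized$dapi
  p3$normalized <- NULL
  p3 <- normalize_profile(p3, "dapi", robust = FALSE)
  expect_equal(p3$normalized$dapi, p$normalized$dapi)
  cst <- toy_stack(function(y, x) 5)
  pcst <- extract_profile(cst, c(0.25, 0.3, 2), c(0.25, 2, 2))
  expect_error(normalize_profile(pcst, "dapi"), "dynamic range")
})

test_that("percent_dapi reads the normalized value with the correct side flag", {
  # linear DAPI ramp 0 -> 100 over 0 -> 10 voxel units of arc
  st <- toy_stack(function(y, x) 100 * y / 3.5, ny = 40, nx = 40)
  p <- extract_profile(st, c(0.25, 0.05, 2), c(0.25, 3.55, 2), step = 0.05)
  p <- normalize_profile(p, "dapi", robust = FALSE)
  co <- percent_dapi(p, 0.33 * max(p$arc))
  expect_equal(co$percent, 33, tolerance = 0.02)
  expect_equal(co$side, "cytoplasmic")
  peak_arc <- p$arc[which.max(p$normalized$dapi)]
  expect_equal(percent_dapi(p, peak_arc)$percent, 100)
  expect_error(percent_dapi(p, max(p$arc) + 1), "outside")
  # Gaussian profile: the cytoplasmic-side half-maximum reads 50%
  mu <- 2; sig <- 0.4
  stg <- toy_stack(function(y, x) 1000 * exp(-((y - mu)^2) / (2 * sig^2)))
  pg <- extract_profile(stg, c(0.25, 0.05, 2), c(0.25, mu, 2), step = 0.01)
  pg <- normalize_profile(pg, "dapi", robust = FALSE)
  half_y <- mu - sig * sqrt(2 * log(2))
  co50 <- percent_dapi(pg, half_y - 0.05)
  expect_equal(co50$percent, 50, tolerance = 1.5)
  expect_equal(co50$side, "cytoplasmic")
})

test_that("marker peak maps to %DAPI with lowest-index tie rule and boundary warning", {
  ramp <- function(y, x) 100 * y / 3.5
  # marker with two equal maxima at y = 1 and y = 2
  marker <- function(y, x) ifelse(abs(y - 1) < 0.051 | abs(y - 2) < 0.051, 50, 10)
  st <- toy_stack(ramp, extra = list(pore = marker))
  p <- extract_profile(st, c(0.25, 0.05, 2), c(0.25, 3.55, 2), step = 0.1)
  p <- normalize_profile(p, "dapi", robust = FALSE)
  mp <- marker_peak_position(p, refine = FALSE)
  expect_equal(mp$arc, 0.90, tolerance = 1e-6)  # first (nearer start) of the ties
  # marker peaked exactly at the DAPI peak reads 100%
  st2 <- toy_stack(ramp, extra = list(pore = function(y, x) exp(-((y - 3.45)^2) / 0.02)))
  p2 <- extract_profile(st2, c(0.25, 0.05, 2), c(0.25, 3.55, 2), step = 0.05)
  p2 <- normalize_profile(p2, "dapi", robust = FALSE)
  expect_gt(marker_peak_position(p2)$percent, 97)
  # monotone marker: warning and boundary value
  st3 <- toy_stack(ramp, extra = list(pore = function(y, x) y))
  p3 <- extract_profile(st3, c(0.25, 0.05, 2), c(0.25, 3.55, 2), step = 0.05)
  p3 <- normalize_profile(p3, "dapi", robust = FALSE)
  expect_warning(marker_peak_position(p3), "no interior maximum")
})

test_that("channel intersection finds the first crossing by linear interpolation", {
  # opposing ramps cross at 50
  st <- toy_stack(function(y, x) 100 * y / 3.5,
                  extra = list(cyto = function(y, x) pmax(100 * (3.5 - y) / 3.5, 0)))
  p <- extract_profile(st, c(0.25, 0.05, 2), c(0.25, 3.45, 2), step = 0.05)
  res <- channel_intersection(p, robust = FALSE)
  expect_equal(res$percent, 50, tolerance = 0.5)
  # marker identical to DAPI: no transversal crossing
  st2 <- toy_stack(function(y, x) 100 * y / 3.5,
                   extra = list(cyto = function(y, x) 100 * y / 3.5))
  p2 <- extract_profile(st2, c(0.25, 0.05, 2), c(0.25, 3.45, 2), step = 0.05)
  expect_error(channel_intersection(p2, robust = FALSE), "no transversal")
  # two shifted logistics: crossing at the analytic midpoint
  a <- 1.2; b <- 2.4; w <- 0.25
  st3 <- toy_stack(function(y, x) 100 / (1 + exp(-(y - a) / w)),
                   extra = list(cyto = function(y, x) 100 / (1 + exp((y - b) / w))))
  p3 <- extract_profile(st3, c(0.25, 0.05, 2), c(0.25, 3.45, 2), step = 0.05)
  res3 <- channel_intersection(p3, robust = FALSE)
  t_cross <- (a + b) / 2
  pct_expected <- 100 / (1 + exp(-(t_cross - a) / w))
  expect_equal(res3$arc, t_cross - 0.05, tolerance = 0.02)
  expect_equal(res3$percent, pct_expected, tolerance = 1)
})

test_that("border calibration aggregates per-profile values", {
  cal <- calibrate_border(c(60, 60, 60))
  expect_equal(cal$mean, 60)
  expect_equal(cal$sd, 0)
  expect_equal(cal$n, 3L)
  cal2 <- calibrate_border(c(20, 40))
  expect_equal(cal2$fraction_below_33, 0.5)
  expect_error(calibrate_border(numeric(0)), "no accepted profiles")
})

test_that("percent_dapi is invariant under positive affine transforms of raw DAPI", {
  sc <- generate_cell_scene(molecule_counts(), seed = 3)
  st <- render_image(sc, optics_params(noise_model = "none"))
  p <- extract_profile(st, c(2.05, 3, 0.3), c(2.05, 3, 3), step = 0.05,
                       channels = "dapi")
  pa <- normalize_profile(p, "dapi")
  pb <- p
  pb$values$dapi <- 3.7 * p$values$dapi + 1200
  pb <- normalize_profile(pb, "dapi")
  q <- 0.37 * max(p$arc)
  expect_equal(percent_dapi(pa, q)$percent, percent_dapi(pb, q)$percent,
               tolerance = 1e-9)
})
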