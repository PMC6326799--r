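#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL means "use current state".
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage child seed from a master seed
#'
#' Deterministic mixing of a master seed with a stage label, so that every
#' stochastic pipeline stage consumes its own reproducible stream. The result
#' is always a valid 32-bit R seed.
#'
#' @param master integer master seed.
#' @param stage character label of the stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  s <- (abs(master) %% m) * 69069 %% m
  as.integer((s + h) %% m)
}

# Euclidean norm of rows of an n x k matrix.
row_norm <- function(m) sqrt(rowSums(m * m))

# Normalised ellipsoid coordinate: 1 on the surface, < 1 inside.
# pos: n x 3 matrix (z, y, x) or length-3 vector.
ellipsoid_u <- function(pos, center, radii) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  sqrt(((pos[, 1] - center[1]) / radii[1])^2 +
       ((pos[, 2] - center[2]) / radii[2])^2 +
       ((pos[, 3] - center[3]) / radii[3])^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
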