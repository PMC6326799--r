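#' Label-free quantitation matrix
#'
#' Minimal proteinGroups-style container: proteins x samples intensities
#' with explicit missingness (`NA`), two balanced conditions, and the
#' three standard quality flags (reverse database hits, potential
#' contaminants, proteins only identified by site).
#'
#' @param ids character protein ids.
#' @param values numeric matrix (proteins x samples), `NA` = missing.
#' @param condition factor/character of length `ncol(values)` with two
#'   levels; the enrichment statistic is condition 2 minus condition 1.
#' @param flags data.frame with logical columns reverse, contaminant,
#'   only_by_site (defaults to all-FALSE).
#' @return An object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(ids, values, condition, flags = NULL) {
  values <- as.matrix(values)
  stopifnot(length(ids) == nrow(values),
            length(condition) == ncol(values))
  condition <- factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions are required")
  if (is.null(flags)) {
    flags <- data.frame(reverse = logical(length(ids)),
                        contaminant = logical(length(ids)),
                        only_by_site = logical(length(ids)))
  }
  stopifnot(nrow(flags) == length(ids),
            all(c("reverse", "contaminant", "only_by_site") %in% names(flags)))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(as.character(condition), "_r",
                               stats::ave(seq_along(condition), condition,
                                          FUN = seq_along))
  }
  structure(list(ids = as.character(ids), values = values,
                 condition = condition, flags = flags),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat("lfq_matrix:", length(x$ids), "proteins x", ncol(x$values),
      "samples (", paste(levels(x$condition), collapse = " vs "), ")\n")
  cat(sprintf("missing values: %.1f%%; flagged rows: %d\n",
              100 * mean(is.na(x$values)),
              sum(x$flags$reverse | x$flags$contaminant | x$flags$only_by_site)))
  invisible(x)
}

#' Write / read an LFQ matrix in the minimal proteinGroups dialect
#'
#' Columns: `Protein IDs`, one `LFQ intensity <sample>` per sample,
#' `Reverse`, `Potential contaminant`, `Only identified by site` (flags
#' marked `+`). Missing intensities are written as 0, the proteinGroups
#' convention, and read back as `NA`.
#'
#' @param x an [lfq_matrix()].
#' @param path TSV file path.
#' @return `write_lfq_tsv` the path, invisibly; `read_lfq_tsv` an
#'   `lfq_matrix`.
#' @export
write_lfq_tsv <- function(x, path) {
  vals <- x$values
  vals[is.na(vals)] <- 0
  df <- data.frame(`Protein IDs` = x$ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) {
    df[[paste("LFQ intensity", colnames(x$values)[j])]] <- vals[, j]
  }
  df[["Reverse"]] <- ifelse(x$flags$reverse, "+", "")
  df[["Potential contaminant"]] <- ifelse(x$flags$contaminant, "+", "")
  df[["Only identified by site"]] <- ifelse(x$flags$only_by_site, "+", "")
  attr_line <- paste0("# condition: ",
                      paste(as.character(x$condition), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfq_tsv
#' @export
read_lfq_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# condition:")) {
    stop("not an LFQ TSV written by write_lfq_tsv (missing condition header): ",
         path)
  }
  condition <- strsplit(sub("^# condition: ", "", first), "\t")[[1]]
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (!length(lfq_cols)) stop("no 'LFQ intensity' columns in ", path)
  vals <- as.matrix(df[, lfq_cols, drop = FALSE])
  colnames(vals) <- sub("^LFQ intensity ", "", lfq_cols)
  vals[vals == 0] <- NA
  flags <- data.frame(reverse = df[["Reverse"]] == "+",
                      contaminant = df[["Potential contaminant"]] == "+",
                      only_by_site = df[["Only identified by site"]] == "+")
  lfq_matrix(df[["Protein IDs"]], vals, condition, flags)
}

#' Ground-truth parameters for the synthetic LFQ simulator
#'
#' The simulator emulates a two-condition (control vs drug-treated
#' nuclei), triplicate label-free experiment: per-protein base abundances
#' are normal on the log2 scale, replicate noise is added within groups,
#' a planted set of proteins is shifted in condition 2, and values go
#' missing with a probability that decreases logistically with abundance
#' (missing-not-at-random, the behaviour down-shifted imputation
#' corrects for).
#'
#' @param n_proteins number of quantified proteins.
#' @param n_enriched number of planted enriched proteins.
#' @param log2_effect_size planted shift (log2) in condition 2.
#' @param base_mean,base_sd log2 abundance distribution of proteins.
#' @param within_sd replicate (within-group) sd on the log2 scale.
#' @param missingness_steepness logistic slope of P(missing) vs log2
#'   abundance (0 disables missingness).
#' @param missingness_mid log2 abundance at which P(missing) = 0.5.
#' @param n_flagged planted reverse/contaminant/only-by-site rows
#'   (appended on top of `n_proteins`).
#' @return A list of class `lfq_ground_truth`.
#' @export
lfq_ground_truth <- function(n_proteins = 200, n_enriched = 20,
                             log2_effect_size = 2,
                             base_mean = 25, base_sd = 2,
                             within_sd = 0.3,
                             missingness_steepness = 1.5,
                             missingness_mid = 22,
                             n_flagged = 6) {
  stopifnot(n_enriched <= n_proteins, n_proteins >= 1,
            within_sd > 0, base_sd > 0, missingness_steepness >= 0)
  structure(list(n_proteins = n_proteins, n_enriched = n_enriched,
                 log2_effect_size = log2_effect_size,
                 base_mean = base_mean, base_sd = base_sd,
                 within_sd = within_sd,
                 missingness_steepness = missingness_steepness,
                 missingness_mid = missingness_mid,
                 n_flagged = n_flagged),
            class = "lfq_ground_truth")
}

#' Generate a synthetic two-condition triplicate LFQ dataset
#'
#' @param truth an [lfq_ground_truth()].
#' @param seed integer seed.
#' @param conditions names of the two conditions.
#' @return list with `matrix` (an [lfq_matrix()] of raw intensities,
#'   2^log2 scale, missing as `NA`) and `truth` (the parameters plus
#'   `enriched_ids` and the flagged ids).
#' @export
generate_lfq_dataset <- function(truth = lfq_ground_truth(), seed = NULL,
                                 conditions = c("ctrl", "treat")) {
  local_seed(seed, {
    n <- truth$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    enriched_ids <- if (truth$n_enriched > 0) {
      sort(sample(ids, truth$n_enriched))
    } else character(0)
    base <- stats::rnorm(n, truth$base_mean, truth$base_sd)
    cond <- rep(conditions, each = 3L)
    log2m <- matrix(rep(base, 6L), nrow = n)
    shift <- ifelse(ids %in% enriched_ids, truth$log2_effect_size, 0)
    log2m[, 4:6] <- log2m[, 4:6] + shift
    log2m <- log2m + stats::rnorm(length(log2m), 0, truth$within_sd)
    if (truth$missingness_steepness > 0) {
      pmiss <- stats::plogis(-(log2m - truth$missingness_mid) *
                             truth$missingness_steepness)
      miss <- matrix(stats::runif(length(log2m)) < pmiss, nrow = n)
      # keep every column estimable: never blank out more than n - 2 rows
      log2m[miss] <- NA
    }
    vals <- 2^log2m
    flags <- data.frame(reverse = logical(n), contaminant = logical(n),
                        only_by_site = logical(n))
    if (truth$n_flagged > 0) {
      kinds <- rep(c("reverse", "contaminant", "only_by_site"),
                   length.out = truth$n_flagged)
      fid <- sprintf("FLAG%02d", seq_len(truth$n_flagged))
      fvals <- 2^matrix(stats::rnorm(truth$n_flagged * 6L, truth$base_mean,
                                     truth$base_sd), nrow = truth$n_flagged)
      fflags <- data.frame(reverse = kinds == "reverse",
                           contaminant = kinds == "contaminant",
                           only_by_site = kinds == "only_by_site")
      ids <- c(ids, fid)
      vals <- rbind(vals, fvals)
      flags <- rbind(flags, fflags)
    }
    colnames(vals) <- paste0(cond, "_r", rep(1:3, 2L))
    out_truth <- truth
    out_truth$enriched_ids <- enriched_ids
    out_truth$flagged_ids <- if (truth$n_flagged > 0) fid else character(0)
    list(matrix = lfq_matrix(ids, vals, cond, flags), truth = out_truth)
  })
}
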