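#' Filter an LFQ matrix
#'
#' Removes flagged rows (reverse hits, potential contaminants, proteins
#' only identified by site) and then keeps proteins quantified in at
#' least `min_valid` of the replicates. With `scope = "any"` (default)
#' the requirement applies to at least one condition, which retains
#' on/off proteins present in only one condition; `scope = "each"`
#' requires it in both.
#'
#' @param x an [lfq_matrix()].
#' @param min_valid minimum quantified replicates (default 2 of 3).
#' @param scope `"any"` or `"each"` condition.
#' @return The filtered `lfq_matrix`; attribute `removed` records the
#'   number of rows dropped by flags and by the valid-value rule.
#' @export
filter_matrix <- function(x, min_valid = 2L, scope = c("any", "each")) {
  scope <- match.arg(scope)
  flagged <- x$flags$reverse | x$flags$contaminant | x$flags$only_by_site
  present <- !is.na(x$values)
  cnt <- vapply(levels(x$condition), function(l) {
    rowSums(present[, x$condition == l, drop = FALSE])
  }, numeric(length(x$ids)))
  enough <- if (scope == "any") {
    apply(cnt >= min_valid, 1L, any)
  } else {
    apply(cnt >= min_valid, 1L, all)
  }
  keep <- !flagged & enough
  out <- lfq_matrix(x$ids[keep], x$values[keep, , drop = FALSE],
                    x$condition, x$flags[keep, , drop = FALSE])
  attr(out, "removed") <- c(flagged = sum(flagged),
                            too_few_values = sum(!flagged & !enough))
  out
}

#' Log2-transform an LFQ matrix
#'
#' @param x an [lfq_matrix()] of raw intensities; all present values must
#'   be strictly positive. Missing values stay missing.
#' @return The `lfq_matrix` with log2 values.
#' @export
log2_transform <- function(x) {
  if (any(x$values <= 0, na.rm = TRUE)) {
    stop("non-positive intensities cannot be log2 transformed")
  }
  x$values <- log2(x$values)
  x
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Missing-not-at-random imputation in the Perseus style: per sample
#' column, missing entries are drawn from a normal distribution whose
#' mean is shifted `downshift` column standard deviations below the
#' observed column mean and whose sd is `width` times the observed column
#' sd. Defaults follow the standard width 0.3 / downshift 1.8 for
#' low-abundance missingness. Observed entries are untouched.
#'
#' @param x an [lfq_matrix()] of log2 values.
#' @param width imputation width as a fraction of the column sd.
#' @param downshift shift below the column mean, in column sds.
#' @param seed integer seed.
#' @return The complete `lfq_matrix`; attribute `imputed` is the logical
#'   missingness pattern that was filled.
#' @export
impute_mnar <- function(x, width = 0.3, downshift = 1.8, seed = NULL) {
  stopifnot(width >= 0, downshift >= 0)
  local_seed(seed, {
    vals <- x$values
    miss <- is.na(vals)
    for (j in seq_len(ncol(vals))) {
      nmiss <- sum(miss[, j])
      if (nmiss == 0L) next
      obs <- vals[!miss[, j], j]
      if (length(obs) < 2L) {
        stop("column ", colnames(vals)[j],
             " has fewer than 2 observed values; cannot impute")
      }
      mu <- mean(obs) - downshift * stats::sd(obs)
      vals[miss[, j], j] <- stats::rnorm(nmiss, mu, width * stats::sd(obs))
    }
    x$values <- vals
    attr(x, "imputed") <- miss
    x
  })
}

# Welch two-sample machinery on a complete matrix, vectorised over rows.
# Returns per-protein means, the Welch standard error, t, df and p.
welch_rows <- function(vals, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(vals[, idx1, drop = FALSE])
  m2 <- rowMeans(vals[, idx2, drop = FALSE])
  v1 <- apply(vals[, idx1, drop = FALSE], 1L, stats::var)
  v2 <- apply(vals[, idx2, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  se <- sqrt(se2)
  t <- (m2 - m1) / se
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(m1 = m1, m2 = m2, se = se, t = t, df = df, p = p)
}

# Balanced assignments of the samples into two pseudo-groups of the
# original sizes, excluding the observed labelling and its mirror: with
# only C(6,3) = 20 balanced splits, keeping the identity would put a hard
# floor of 2/20 on the estimated FDR whenever real effects exist.
# Columns index samples of pseudo-group 1.
balanced_splits <- function(condition) {
  n <- length(condition)
  idx1 <- which(condition == levels(condition)[1])
  splits <- utils::combn(n, length(idx1))
  same <- apply(splits, 2L, function(s) {
    setequal(s, idx1) || setequal(s, setdiff(seq_len(n), idx1))
  })
  splits[, !same, drop = FALSE]
}

#' S0-moderated Welch test with permutation FDR
#'
#' The SAM-style enrichment test: per protein the moderated statistic
#' `d = (mean2 - mean1) / (se_welch + s0)` is compared with a null
#' distribution obtained by randomly relabelling the sample columns into
#' balanced pseudo-groups. The significance frontier is the smallest
#' cutoff `c` (among the observed `|d|`) at which the estimated FDR —
#' mean permutation exceedance count divided by observed exceedance
#' count — drops to `fdr`; proteins with `|d|` at or above the frontier
#' are called significant (two-sided, symmetric frontier). With `s0 = 0`
#' the statistic is exactly the Welch t.
#'
#' @param x a complete (post-imputation) [lfq_matrix()] of log2 values.
#' @param s0 variance-stabilising offset added to the standard error
#'   (default 0.5).
#' @param n_randomizations number of random relabelings (default 250);
#'   sampled with replacement from the balanced splits of the six
#'   columns. `n_randomizations = NULL` enumerates all balanced splits
#'   exactly.
#' @param fdr target false discovery rate (default 0.05).
#' @param seed integer seed for the relabelling draw.
#' @param fdr_estimator `"mean"` (default) or `"median"` permutation
#'   exceedance count.
#' @return An `enrichment_result`: data.frame `table` with per-protein
#'   log2 fold change (condition 2 minus condition 1), moderated `d`,
#'   Welch `t`, `p`, `significant`, `direction`; plus the significance
#'   `frontier` and run metadata.
#' @export
sam_welch_test <- function(x, s0 = 0.5, n_randomizations = 250, fdr = 0.05,
                           seed = NULL, fdr_estimator = c("mean", "median")) {
  fdr_estimator <- match.arg(fdr_estimator)
  stopifnot(s0 >= 0, fdr > 0, fdr < 1)
  vals <- x$values
  if (anyNA(vals)) stop("matrix has missing values; impute first")
  lev <- levels(x$condition)
  idx1 <- which(x$condition == lev[1])
  idx2 <- which(x$condition == lev[2])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("at least two samples per condition are required")
  }
  w <- welch_rows(vals, idx1, idx2)
  if (s0 == 0 && any(w$se == 0)) {
    stop("degenerate variance with s0 = 0; use s0 > 0")
  }
  d_obs <- (w$m2 - w$m1) / (w$se + s0)

  splits <- balanced_splits(x$condition)
  n_splits <- ncol(splits)
  pick <- local_seed(seed, {
    if (is.null(n_randomizations)) seq_len(n_splits)
    else sample.int(n_splits, n_randomizations, replace = TRUE)
  })
  all_idx <- seq_along(x$condition)
  perm_abs <- lapply(pick, function(k) {
    g1 <- splits[, k]
    g2 <- setdiff(all_idx, g1)
    wp <- welch_rows(vals, g1, g2)
    abs((wp$m2 - wp$m1) / (wp$se + s0))
  })

  # estimated FDR at every observed |d| cutoff
  cuts <- sort(unique(abs(d_obs)), decreasing = TRUE)
  obs_exceed <- vapply(cuts, function(c) sum(abs(d_obs) >= c), numeric(1))
  perm_exceed <- vapply(cuts, function(c) {
    counts <- vapply(perm_abs, function(pa) sum(pa >= c), numeric(1))
    if (fdr_estimator == "mean") mean(counts) else stats::median(counts)
  }, numeric(1))
  est_fdr <- perm_exceed / pmax(obs_exceed, 1)
  ok <- which(est_fdr <= fdr)
  frontier <- if (length(ok)) min(cuts[ok]) else Inf
  significant <- abs(d_obs) >= frontier

  table <- data.frame(
    protein = x$ids,
    log2fc = w$m2 - w$m1,
    d = d_obs,
    t = w$t,
    p = w$p,
    significant = significant,
    direction = ifelse(d_obs > 0, "up", ifelse(d_obs < 0, "down", "none")),
    stringsAsFactors = FALSE)
  structure(list(table = table, frontier = frontier, s0 = s0,
                 n_randomizations = length(pick), fdr_level = fdr,
                 fdr_estimator = fdr_estimator, seed = seed,
                 conditions = lev,
                 n_significant = sum(significant),
                 n_up = sum(significant & d_obs > 0),
                 n_down = sum(significant & d_obs < 0)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment (%s vs %s): %d significant of %d proteins (%d up, %d down)\n",
    x$conditions[2], x$conditions[1], x$n_significant, nrow(x$table),
    x$n_up, x$n_down))
  cat(sprintf("s0 = %.2f, %d randomizations, FDR = %.2f, frontier |d| = %.3g\n",
              x$s0, x$n_randomizations, x$fdr_level, x$frontier))
  invisible(x)
}

#' Volcano table of an enrichment result
#'
#' One row per protein with the columns needed to re-plot a volcano:
#' log2 fold change, -log10 Welch p, significance call and direction.
#'
#' @param result an `enrichment_result` from [sam_welch_test()].
#' @param path optional TSV output path.
#' @return The data.frame, invisibly when `path` is given.
#' @export
volcano_table <- function(result, path = NULL) {
  df <- data.frame(protein = result$table$protein,
                   log2fc = result$table$log2fc,
                   neg_log10_p = -log10(result$table$p),
                   significant = result$table$significant,
                   direction = result$table$direction,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Volcano plot
#'
#' @param result an `enrichment_result`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_volcano <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_volcano requires the ggplot2 package")
  }
  df <- volcano_table(result)
  df$call <- ifelse(!df$significant, "not significant",
                    ifelse(df$direction == "up", "enriched", "depleted"))
  ggplot2::ggplot(df, ggplot2::aes(x = log2fc, y = neg_log10_p,
                                   colour = call)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(
      "enriched" = "red3", "depleted" = "steelblue",
      "not significant" = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p (Welch)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
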