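#' Scan a protein for Q-rich regions
#'
#' The sequence is divided into consecutive non-overlapping 60-mers from
#' the first residue (or from `offset + 1`); a window is a Q-rich region
#' if it contains at least `min_count` of the scored residue (glutamine
#' by default). The trailing remainder shorter than one window is not
#' scored. The density is the number of qualifying windows per 100 amino
#' acids of the full protein length.
#'
#' @param sequence a single amino-acid sequence (character string or a
#'   `Biostrings::AAString`); ambiguity codes count as non-matching.
#' @param window window length in residues (default 60).
#' @param min_count minimum residue count per window (default 7).
#' @param residue scored residue (default `"Q"`).
#' @param offset scanning-frame offset in residues (default 0: the first
#'   window starts at residue 1).
#' @return A list of class `qrich_score`: `length`, `n_windows`
#'   (windows scanned), `n_qrich`, `density` (regions per 100 aa).
#' @export
qrich_scan <- function(sequence, window = 60L, min_count = 7L,
                       residue = "Q", offset = 0L) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L, window >= 1L, min_count >= 1L,
            nchar(residue) == 1L, offset >= 0L)
  len <- nchar(sequence)
  if (len == 0L) stop("empty sequence")
  usable <- len - offset
  k <- if (usable >= window) usable %/% window else 0L
  n_qrich <- 0L
  if (k > 0L) {
    body <- substr(sequence, offset + 1L, offset + k * window)
    chars <- strsplit(body, "", fixed = TRUE)[[1]]
    hits <- matrix(chars == residue, nrow = window)
    n_qrich <- sum(colSums(hits) >= min_count)
  }
  structure(list(length = len, n_windows = k, n_qrich = n_qrich,
                 density = n_qrich / len * 100),
            class = "qrich_score")
}

#' Q-rich scores for a set of sequences
#'
#' @param sequences named character vector or `Biostrings::AAStringSet`.
#' @inheritParams qrich_scan
#' @return data.frame(protein, length, n_qrich, density).
#' @export
qrich_scan_set <- function(sequences, window = 60L, min_count = 7L,
                           residue = "Q", offset = 0L) {
  seqs <- as.character(sequences)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- qrich_scan(seqs[i], window, min_count, residue, offset)
    data.frame(protein = ids[i], length = s$length, n_qrich = s$n_qrich,
               density = s$density, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare Q-rich densities between two protein groups
#'
#' Sorts each group's densities in descending order (the display used to
#' contrast an enriched protein set against control proteins) and
#' reports per-group mean densities.
#'
#' @param scores_a,scores_b data.frames from [qrich_scan_set()].
#' @return list with `sorted_a`, `sorted_b` (data.frames sorted by
#'   descending density) and `summary` (group means).
#' @export
qrich_compare <- function(scores_a, scores_b) {
  stopifnot(nrow(scores_a) > 0L, nrow(scores_b) > 0L)
  sort_desc <- function(df) df[order(-df$density, df$protein), , drop = FALSE]
  list(sorted_a = sort_desc(scores_a),
       sorted_b = sort_desc(scores_b),
       summary = data.frame(group = c("a", "b"),
                            mean_density = c(mean(scores_a$density),
                                             mean(scores_b$density)),
                            n = c(nrow(scores_a), nrow(scores_b))))
}

# Top hit of a hit table per query: lowest e-value, ties broken by
# highest bit score, then lexicographic subject id.
top_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, hits$e_value, -hits$bit_score, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query), , drop = FALSE]
}

#' Reciprocal-best-hit homology classification
#'
#' For each protein and each taxon, take the top forward hit (lowest
#' e-value; ties resolve to the highest bit score, then the
#' lexicographically smallest subject id) and test whether the top
#' reverse hit of that subject is the original protein; the protein has
#' a homologue in the taxon if so and if the e-value condition
#' (`e < evalue_cutoff`, applied by default to the reverse hit) holds.
#' Proteins are then categorised by how many of the taxa carry a
#' homologue: none makes the protein `unique`, otherwise
#' `shared_in_<k>`.
#'
#' @param forward_hits data.frame(query, subject, e_value, bit_score,
#'   taxon): hits of the study proteins against each taxon's proteome.
#' @param reverse_hits data.frame of the same shape: hits of the taxon
#'   proteins back against the study proteome (query = taxon protein,
#'   subject = study protein).
#' @param proteins protein universe; defaults to the forward queries.
#'   Proteins absent from the tables have no homologues.
#' @param evalue_cutoff significance cutoff (default 1e-5).
#' @param cutoff_on apply the cutoff to the `"reverse"` hit (default,
#'   the literal reading of the classification rule), the `"forward"`
#'   hit, or `"both"`.
#' @return data.frame with one row per protein: a logical column per
#'   taxon, `n_taxa`, and `category`.
#' @export
rbh_classify <- function(forward_hits, reverse_hits, proteins = NULL,
                         evalue_cutoff = 1e-5,
                         cutoff_on = c("reverse", "forward", "both")) {
  cutoff_on <- match.arg(cutoff_on)
  need <- c("query", "subject", "e_value", "bit_score", "taxon")
  stopifnot(all(need %in% names(forward_hits)),
            all(need %in% names(reverse_hits)),
            all(forward_hits$e_value >= 0),
            all(reverse_hits$e_value >= 0))
  proteins <- proteins %||% sort(unique(forward_hits$query))
  taxa <- sort(unique(c(forward_hits$taxon, reverse_hits$taxon)))
  out <- data.frame(protein = proteins, stringsAsFactors = FALSE)
  for (tx in taxa) {
    fw <- top_hits(forward_hits[forward_hits$taxon == tx, , drop = FALSE])
    rv <- top_hits(reverse_hits[reverse_hits$taxon == tx, , drop = FALSE])
    flag <- vapply(proteins, function(p) {
      f <- fw[fw$query == p, , drop = FALSE]
      if (nrow(f) == 0L) return(FALSE)
      r <- rv[rv$query == f$subject, , drop = FALSE]
      if (nrow(r) == 0L || r$subject != p) return(FALSE)
      switch(cutoff_on,
             reverse = r$e_value < evalue_cutoff,
             forward = f$e_value < evalue_cutoff,
             both = r$e_value < evalue_cutoff && f$e_value < evalue_cutoff)
    }, logical(1))
    out[[tx]] <- unname(flag)
  }
  out$n_taxa <- if (length(taxa)) {
    rowSums(as.matrix(out[, taxa, drop = FALSE]))
  } else rep(0L, nrow(out))
  out$category <- ifelse(out$n_taxa == 0L, "unique",
                         paste0("shared_in_", out$n_taxa))
  out
}

#' Read / write tabular hit files
#'
#' The 12-column tabular alignment format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score), optionally with a 13th taxon
#' column; a taxon label can instead be supplied for the whole file.
#'
#' @param path TSV path without header lines.
#' @param taxon taxon label applied to all rows when the file has 12
#'   columns.
#' @return data.frame(query, subject, pident, length, mismatch, gapopen,
#'   qstart, qend, sstart, send, e_value, bit_score, taxon).
#' @export
read_hit_table <- function(path, taxon = NULL) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "e_value", "bit_score")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 12L) {
    names(df) <- cols
    if (is.null(taxon)) stop("12-column hit table needs a `taxon` label")
    df$taxon <- taxon
  } else if (ncol(df) == 13L) {
    names(df) <- c(cols, "taxon")
  } else {
    stop("hit table must have 12 or 13 tab-separated columns, found ",
         ncol(df), " in ", path)
  }
  if (any(df$e_value < 0)) stop("negative e-values in ", path)
  df
}

#' @rdname read_hit_table
#' @param hits data.frame in the layout returned by `read_hit_table`.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
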