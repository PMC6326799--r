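# Amino-acid alphabet without the scored residue; planted and background
# windows control the residue count exactly.
aa_alphabet <- function(exclude = "Q") {
  setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], exclude)
}

#' Generate synthetic protein sequences with planted Q-rich regions
#'
#' Sequences are built window by window on the scanning frame: background
#' 60-mers carry strictly fewer than `min_count` of the scored residue
#' (drawn binomially and capped), planted 60-mers carry at least
#' `min_count`. The trailing remainder contains none. Window counts per
#' protein are therefore exact ground truth for the scanner.
#'
#' @param n number of proteins.
#' @param lengths protein lengths in residues (recycled); proteins with
#'   planted regions must be at least one window long.
#' @param planted number of planted Q-rich windows per protein
#'   (recycled).
#' @param window,min_count,residue scanning parameters, see
#'   [qrich_scan()].
#' @param background_rate per-residue background frequency of the scored
#'   residue (capped below `min_count` per window).
#' @param seed integer seed.
#' @return list with `sequences` (a `Biostrings::AAStringSet`) and
#'   `truth` (data.frame protein, length, n_planted).
#' @export
generate_protein_sequences <- function(n, lengths = 300L, planted = 0L,
                                       window = 60L, min_count = 7L,
                                       residue = "Q",
                                       background_rate = 0.02,
                                       seed = NULL) {
  lengths <- rep_len(as.integer(lengths), n)
  planted <- rep_len(as.integer(planted), n)
  stopifnot(all(lengths >= 1L), all(planted >= 0L))
  if (any(planted > lengths %/% window)) {
    stop("more planted windows requested than fit in the protein")
  }
  bg <- aa_alphabet(residue)
  local_seed(seed, {
    make_window <- function(nq) {
      chars <- sample(bg, window, replace = TRUE)
      if (nq > 0L) chars[sample.int(window, nq)] <- residue
      paste(chars, collapse = "")
    }
    seqs <- character(n)
    for (i in seq_len(n)) {
      k <- lengths[i] %/% window
      rem <- lengths[i] - k * window
      rich <- logical(k)
      if (planted[i] > 0L) rich[sample.int(k, planted[i])] <- TRUE
      wins <- vapply(seq_len(k), function(j) {
        nq <- if (rich[j]) {
          min(window, min_count + stats::rpois(1L, 1.5))
        } else {
          min(stats::rbinom(1L, window, background_rate), min_count - 1L)
        }
        make_window(nq)
      }, character(1))
      tail <- if (rem > 0L) {
        paste(sample(bg, rem, replace = TRUE), collapse = "")
      } else ""
      seqs[i] <- paste0(paste(wins, collapse = ""), tail)
    }
    ids <- sprintf("SYN%04d", seq_len(n))
    names(seqs) <- ids
    list(sequences = Biostrings::AAStringSet(seqs),
         truth = data.frame(protein = ids, length = lengths,
                            n_planted = planted, stringsAsFactors = FALSE))
  })
}

#' Generate ground-truthed reciprocal-hit tables
#'
#' Builds forward and reverse tabular hit records for a protein set
#' against several taxa with a known homologue truth: true homologues get
#' mutually-best hit pairs below the e-value cutoff; a share of the
#' non-homologues get decoy hits that fail reciprocity (the reverse top
#' hit points at a different protein) or fail the e-value condition, so
#' the classifier's negative paths are exercised too.
#'
#' @param proteins character protein ids.
#' @param taxa taxon labels.
#' @param p_homologue probability that a protein has a homologue in a
#'   taxon (recycled over taxa).
#' @param p_decoy probability that a non-homologue gets a decoy hit.
#' @param evalue_cutoff the classification cutoff the truth respects.
#' @param seed integer seed.
#' @return list with `forward`, `reverse` (hit data.frames) and `truth`
#'   (logical matrix proteins x taxa).
#' @export
generate_homology_tables <- function(proteins,
                                     taxa = c("scerevisiae", "celegans",
                                              "mmusculus", "pfalciparum"),
                                     p_homologue = 0.2, p_decoy = 0.3,
                                     evalue_cutoff = 1e-5, seed = NULL) {
  p_homologue <- rep_len(p_homologue, length(taxa))
  local_seed(seed, {
    fw <- list(); rv <- list()
    truth <- matrix(FALSE, length(proteins), length(taxa),
                    dimnames = list(proteins, taxa))
    hit <- function(q, s, e, b, tx) {
      data.frame(query = q, subject = s, e_value = e, bit_score = b,
                 taxon = tx, stringsAsFactors = FALSE)
    }
    for (ti in seq_along(taxa)) {
      tx <- taxa[ti]
      for (p in proteins) {
        if (stats::runif(1) < p_homologue[ti]) {
          truth[p, tx] <- TRUE
          orth <- paste0(tx, "_orth_", p)
          e <- 10^stats::runif(1, -30, -8)   # comfortably below cutoff
          fw[[length(fw) + 1L]] <- hit(p, orth, e, 200 + stats::runif(1, 0, 300), tx)
          rv[[length(rv) + 1L]] <- hit(orth, p, 10^stats::runif(1, -30, -8),
                                       200 + stats::runif(1, 0, 300), tx)
        } else if (stats::runif(1) < p_decoy) {
          decoy <- paste0(tx, "_decoy_", p)
          if (stats::runif(1) < 0.5) {
            # non-reciprocal: reverse top hit points elsewhere
            other <- sample(setdiff(proteins, p), 1L)
            fw[[length(fw) + 1L]] <- hit(p, decoy, 10^stats::runif(1, -20, -8),
                                         150, tx)
            rv[[length(rv) + 1L]] <- hit(decoy, other, 10^stats::runif(1, -20, -8),
                                         150, tx)
          } else {
            # reciprocal but weak: reverse e-value above the cutoff
            fw[[length(fw) + 1L]] <- hit(p, decoy, 10^stats::runif(1, -20, -8),
                                         120, tx)
            rv[[length(rv) + 1L]] <- hit(decoy, p,
                                         10^stats::runif(1, log10(evalue_cutoff), 0),
                                         120, tx)
          }
        }
      }
    }
    empty <- data.frame(query = character(), subject = character(),
                        e_value = numeric(), bit_score = numeric(),
                        taxon = character(), stringsAsFactors = FALSE)
    list(forward = if (length(fw)) do.call(rbind, fw) else empty,
         reverse = if (length(rv)) do.call(rbind, rv) else empty,
         truth = truth)
  })
}

#' Write / read protein sequences as FASTA
#'
#' Thin wrappers over Biostrings, kept so every pipeline format has a
#' reader/writer pair in one place.
#'
#' @param sequences an `AAStringSet` or named character vector.
#' @param path FASTA path.
#' @export
write_fasta <- function(sequences, path) {
  if (!inherits(sequences, "AAStringSet")) {
    sequences <- Biostrings::AAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readAAStringSet(path)
}
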