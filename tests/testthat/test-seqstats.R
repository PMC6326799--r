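# Brute-force window oracle, independent of the scanner's implementation:
# slice each window explicitly and count matches.
qrich_oracle <- function(seq, window = 60L, min_count = 7L, residue = "Q",
                         offset = 0L) {
  len <- nchar(seq)
  k <- max((len - offset) %/% window, 0L)
  if (len - offset < window) k <- 0L
  n <- 0L
  for (j in seq_len(k)) {
    win <- substr(seq, offset + (j - 1L) * window + 1L, offset + j * window)
    if (sum(strsplit(win, "")[[1]] == residue) >= min_count) n <- n + 1L
  }
  n
}

random_protein <- function(len, q_rate = 0.08) {
  paste(sample(c(strsplit("ACDEFGHIKLMNPRSTVWY", "")[[1]], rep("Q", 3)),
               len, replace = TRUE,
               prob = c(rep((1 - q_rate) / 19, 19), rep(q_rate / 3, 3))),
        collapse = "")
}

test_that("the 60-mer window rule counts at the >= 7 boundary", {
  win7 <- paste0(strrep("A", 53), strrep("Q", 7))
  expect_equal(qrich_scan(win7)$n_qrich, 1L)
  win6 <- paste0(strrep("A", 54), strrep("Q", 6))
  expect_equal(qrich_scan(win6)$n_qrich, 0L)
  # density: one qualifying window in a 300-aa protein
  prot <- paste0(win7, strrep("A", 240))
  sc <- qrich_scan(prot)
  expect_equal(sc$n_qrich, 1L)
  expect_equal(sc$density, 1 / 300 * 100)
  # trailing remainder is not scored even if Q-rich
  tail_rich <- paste0(strrep("A", 60), strrep("Q", 30))
  expect_equal(qrich_scan(tail_rich)$n_qrich, 0L)
  expect_error(qrich_scan(""), "empty")
})

test_that("the scanner equals the brute-force slicing oracle on random sequences", {
  set.seed(31)
  for (rep in 1:150) {
    len <- sample(1:1000, 1)
    s <- random_protein(len)
    expect_equal(qrich_scan(s)$n_qrich, qrich_oracle(s))
  }
  # frame offset shifts the windows
  set.seed(32)
  s <- random_protein(500, q_rate = 0.12)
  for (off in c(0L, 7L, 59L)) {
    expect_equal(qrich_scan(s, offset = off)$n_qrich, qrich_oracle(s, offset = off))
  }
})

test_that("self-concatenation doubles the window count and preserves density", {
  set.seed(33)
  s <- random_protein(300, q_rate = 0.12)
  one <- qrich_scan(s)
  two <- qrich_scan(paste0(s, s))
  expect_equal(two$n_qrich, 2L * one$n_qrich)
  expect_equal(two$density, one$density)
})

test_that("group comparison sorts densities and separates planted from background", {
  a <- generate_protein_sequences(8, 300, planted = 2, seed = 34)
  b <- generate_protein_sequences(8, 300, planted = 0, seed = 35)
  cmp <- qrich_compare(qrich_scan_set(a$sequences), qrich_scan_set(b$sequences))
  expect_true(all(diff(cmp$sorted_a$density) <= 0))
  expect_gt(cmp$summary$mean_density[1], cmp$summary$mean_density[2])
  zero <- qrich_scan_set(b$sequences)
  expect_equal(qrich_compare(zero, zero)$summary$mean_density, c(0, 0))
})

hit <- function(q, s, e, b, tx = "yeast") {
  data.frame(query = q, subject = s, e_value = e, bit_score = b, taxon = tx,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits follow the reciprocity and e-value rules", {
  fw <- hit("A", "B", 1e-10, 200)
  rv <- hit("B", "A", 1e-8, 180)
  cls <- rbh_classify(fw, rv, proteins = "A")
  expect_true(cls$yeast)
  expect_equal(cls$category, "shared_in_1")
  # reciprocal pair but the reverse e-value misses the cutoff
  rv2 <- hit("B", "A", 1e-3, 180)
  expect_false(rbh_classify(fw, rv2, proteins = "A")$yeast)
  # non-reciprocal: reverse top hit points at another protein
  rv3 <- hit("B", "C", 1e-12, 300)
  expect_false(rbh_classify(fw, rv3, proteins = "A")$yeast)
  # protein without hits is unique
  cls4 <- rbh_classify(fw, rv, proteins = c("A", "Z"))
  expect_equal(cls4$category[cls4$protein == "Z"], "unique")
  # cutoff applied to the forward hit instead when configured
  fw5 <- hit("A", "B", 1e-3, 200)
  rv5 <- hit("B", "A", 1e-10, 200)
  expect_true(rbh_classify(fw5, rv5, proteins = "A")$yeast)
  expect_false(rbh_classify(fw5, rv5, proteins = "A",
                            cutoff_on = "forward")$yeast)
})

test_that("top-hit ties resolve by bit score then subject id", {
  fw <- rbind(hit("A", "B1", 1e-10, 100), hit("A", "B2", 1e-10, 250))
  rv <- rbind(hit("B1", "A", 1e-9, 100), hit("B2", "C", 1e-9, 100))
  # B2 wins on bit score; its reverse hit is not A
  expect_false(rbh_classify(fw, rv, proteins = "A")$yeast)
  fw2 <- rbind(hit("A", "B2", 1e-10, 100), hit("A", "B1", 1e-10, 100))
  rv2 <- rbind(hit("B1", "A", 1e-9, 100), hit("B2", "C", 1e-9, 100))
  # full tie: lexicographically smaller subject B1 wins, which is reciprocal
  expect_true(rbh_classify(fw2, rv2, proteins = "A")$yeast)
})

test_that("categories count taxa with homologues and cover all proteins", {
  taxa <- c("t1", "t2", "t3", "t4")
  fw <- do.call(rbind, lapply(taxa, function(tx) hit("A", paste0("o", tx), 1e-10, 200, tx)))
  rv <- do.call(rbind, lapply(taxa, function(tx) hit(paste0("o", tx), "A", 1e-10, 200, tx)))
  cls <- rbh_classify(fw, rv, proteins = c("A", "B"))
  expect_equal(cls$category[cls$protein == "A"], "shared_in_4")
  expect_equal(cls$category[cls$protein == "B"], "unique")
  expect_equal(nrow(cls), 2L)
  # histogram over categories sums to the protein universe
  hom <- generate_homology_tables(sprintf("P%02d", 1:30), seed = 36)
  cls2 <- rbh_classify(hom$forward, hom$reverse, proteins = sprintf("P%02d", 1:30))
  expect_equal(sum(table(cls2$category)), 30L)
  expect_equal(as.matrix(cls2[, colnames(hom$truth)]) == TRUE,
               hom$truth, ignore_attr = TRUE)
})

test_that("rbh classification is symmetric under swapping tables and roles", {
  hom <- generate_homology_tables(sprintf("P%02d", 1:12), taxa = "t1",
                                  p_homologue = 0.5, seed = 37)
  cls <- rbh_classify(hom$forward, hom$reverse,
                      proteins = sprintf("P%02d", 1:12))
  # swap: classify the orthologue set from the other side
  orths <- unique(hom$forward$subject[grepl("orth", hom$forward$subject)])
  cls_rev <- rbh_classify(hom$reverse, hom$forward, proteins = orths)
  expect_true(all(cls_rev$t1))
  expect_equal(sum(cls$t1), length(orths))
})
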