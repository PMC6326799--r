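# Small deterministic matrix builders.
toy_lfq <- function(values, ids = NULL, flags = NULL) {
  values <- as.matrix(values)
  lfq_matrix(ids %||% paste0("p", seq_len(nrow(values))), values,
             rep(c("ctrl", "treat"), each = 3), flags)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("filtering removes flagged rows and applies the 2-of-3 valid-value rule", {
  vals <- rbind(c(2, 2, 2, 4, 4, 4),      # complete
                c(2, 2, NA, NA, NA, NA),  # 2/3 in ctrl only -> kept (scope any)
                c(2, NA, NA, 4, NA, NA),  # 1/3 and 1/3 -> removed
                c(2, 2, 2, 4, 4, 4))      # complete but flagged
  flags <- data.frame(reverse = c(FALSE, FALSE, FALSE, TRUE),
                      contaminant = FALSE, only_by_site = FALSE)
  x <- toy_lfq(vals, flags = flags)
  f <- filter_matrix(x)
  expect_equal(f$ids, c("p1", "p2"))
  expect_equal(unname(attr(f, "removed")["flagged"]), 1)
  expect_equal(unname(attr(f, "removed")["too_few_values"]), 1)
  # scope = "each" drops the on/off protein too
  f2 <- filter_matrix(x, scope = "each")
  expect_equal(f2$ids, "p1")
})

test_that("log2 transform maps intensities elementwise and keeps missingness", {
  x <- toy_lfq(rbind(c(1024, 2, 1, 8, NA, 4)))
  lt <- log2_transform(x)
  expect_equal(lt$values[1, ], c(10, 1, 0, 3, NA, 2), ignore_attr = TRUE)
  bad <- toy_lfq(rbind(c(-1, 2, 2, 4, 4, 4)))
  expect_error(log2_transform(bad), "non-positive")
})

test_that("MNAR imputation draws from the down-shifted normal with the stated moments", {
  # complete column untouched
  x <- toy_lfq(rbind(c(2, 2, 2, 4, 4, 4)))
  xi <- impute_mnar(x, seed = 1)
  expect_identical(xi$values, x$values)
  # moment check: column with mean 25, sd 1, many missing entries
  set.seed(2)
  n <- 2e4
  col <- c(rnorm(n / 2, 25, 1), rep(NA, n / 2))
  vals <- cbind(col, col, col, col, col, col)
  big <- lfq_matrix(paste0("q", seq_len(n)), vals,
                    rep(c("a", "b"), each = 3))
  bi <- impute_mnar(big, width = 0.3, downshift = 1.8, seed = 3)
  obs <- vals[1:(n / 2), 1]
  imp <- bi$values[(n / 2 + 1):n, 1]
  expect_equal(mean(imp), mean(obs) - 1.8 * sd(obs), tolerance = 0.01)
  expect_equal(sd(imp), 0.3 * sd(obs), tolerance = 0.01)
  # degenerate width: all imputed values identical
  b0 <- impute_mnar(big, width = 0, downshift = 1.8, seed = 4)
  imp0 <- b0$values[(n / 2 + 1):n, 1]
  expect_true(all(abs(imp0 - (mean(obs) - 1.8 * sd(obs))) < 1e-12))
  # a column with fewer than two observed values cannot be imputed
  tiny <- toy_lfq(rbind(c(2, NA, NA, 4, 4, 4), c(NA, NA, NA, 4, 4, 4)))
  expect_error(impute_mnar(tiny, seed = 5), "fewer than 2 observed")
})

test_that("with s0 = 0 the moderated statistic is exactly the Welch t", {
  set.seed(6)
  for (rep in 1:3) {
    vals <- matrix(rnorm(120, 25, 1), nrow = 20)
    x <- toy_lfq(vals)
    r <- sam_welch_test(x, s0 = 0, n_randomizations = 5, seed = rep)
    t_oracle <- vapply(seq_len(20), function(i) {
      unname(t.test(vals[i, 4:6], vals[i, 1:3])$statistic)
    }, numeric(1))
    expect_equal(r$table$d, t_oracle, tolerance = 1e-10)
    expect_equal(r$table$t, t_oracle, tolerance = 1e-10)
  }
  # degenerate variance errors only when s0 = 0
  cst <- toy_lfq(rbind(c(2, 2, 2, 4, 4, 4)))
  expect_error(sam_welch_test(cst, s0 = 0, n_randomizations = 5, seed = 1),
               "degenerate")
  expect_silent(sam_welch_test(cst, s0 = 0.5, n_randomizations = 5, seed = 1))
})

test_that("|d| is non-increasing in s0 and label swap negates the statistics", {
  set.seed(7)
  vals <- matrix(rnorm(180, 25, 1), nrow = 30)
  x <- toy_lfq(vals)
  d1 <- sam_welch_test(x, s0 = 0.2, n_randomizations = 5, seed = 1)$table$d
  d2 <- sam_welch_test(x, s0 = 0.8, n_randomizations = 5, seed = 1)$table$d
  expect_true(all(abs(d2) <= abs(d1) + 1e-12))
  swapped <- lfq_matrix(x$ids, x$values[, c(4:6, 1:3)],
                        rep(c("ctrl", "treat"), each = 3))
  rs <- sam_welch_test(swapped, n_randomizations = 5, seed = 1)
  ro <- sam_welch_test(x, n_randomizations = 5, seed = 1)
  expect_equal(rs$table$d, -ro$table$d, tolerance = 1e-12)
  expect_equal(rs$table$log2fc, -ro$table$log2fc, tolerance = 1e-12)
})

test_that("planted enrichment at the study effect size is recovered at controlled FDR", {
  recall <- c(); fdrs <- c()
  for (s in 1:3) {
    d <- generate_lfq_dataset(lfq_ground_truth(), seed = 30 + s)
    m <- impute_mnar(log2_transform(filter_matrix(d$matrix)), seed = 40 + s)
    r <- sam_welch_test(m, seed = 50 + s)
    called <- r$table$protein[r$table$significant]
    recall <- c(recall, mean(d$truth$enriched_ids %in% called))
    fdrs <- c(fdrs, if (length(called)) {
      mean(!called %in% d$truth$enriched_ids)
    } else 0)
  }
  expect_gte(mean(recall), 0.8)
  expect_lte(mean(fdrs), 0.15)
})

test_that("exact enumeration mode is deterministic and matches itself", {
  set.seed(8)
  vals <- matrix(rnorm(120, 25, 1), nrow = 20)
  x <- toy_lfq(vals)
  r1 <- sam_welch_test(x, n_randomizations = NULL)
  r2 <- sam_welch_test(x, n_randomizations = NULL)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$n_randomizations, 18L)  # 20 balanced splits minus identity pair
})

test_that("the volcano table mirrors the enrichment result", {
  set.seed(9)
  vals <- matrix(rnorm(60, 25, 1), nrow = 10)
  vals[1, 4:6] <- vals[1, 4:6] + 3
  x <- toy_lfq(vals)
  r <- sam_welch_test(x, n_randomizations = 10, seed = 1)
  v <- volcano_table(r)
  expect_equal(nrow(v), 10)
  expect_equal(v$significant, r$table$significant)
  expect_equal(v$log2fc, r$table$log2fc)
  # equal means give zero fold change
  same <- toy_lfq(rbind(c(2, 3, 4, 4, 3, 2)))
  rs <- sam_welch_test(same, n_randomizations = 5, seed = 1)
  expect_equal(rs$table$log2fc, 0)
})
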