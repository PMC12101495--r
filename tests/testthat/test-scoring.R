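# Confusion-matrix scoring, correlation, calibration, and the tuning grid.

calls_df <- function(samples, categories, present) {
  data.frame(sample_id = samples, category = categories, present = present,
             stringsAsFactors = FALSE)
}

test_that("confusion counts and rates follow the forced arithmetic", {
  truth <- data.frame(sample_id = rep(c("s1", "s2"), each = 5),
                      category = rep(letters[1:5], 2),
                      true_cell_fraction = c(0.1, 0.2, 0, 0, 0.05,
                                             0, 0, 0, 0, 0))
  # s1: a TP, b FN, c FP, d TN, e TP; s2: all absent -> 5 TN
  calls <- calls_df(rep(c("s1", "s2"), each = 5), rep(letters[1:5], 2),
                    c(TRUE, FALSE, TRUE, FALSE, TRUE, rep(FALSE, 5)))
  sc <- score_attribution(calls, truth)
  expect_identical(c(sc$tp, sc$fp, sc$fn, sc$tn), c(2L, 1L, 1L, 6L))
  expect_equal(sc$sensitivity, 2 / 3)
  expect_equal(sc$specificity, 6 / 7)
  expect_equal(sc$npv, 6 / 7)
  expect_equal(sc$ppv, 2 / 3)
  expect_identical(sc$tp + sc$fp + sc$fn + sc$tn, nrow(truth))
})

test_that("perfect calls score 1; zero denominators report NA, not 0", {
  truth <- data.frame(sample_id = "s1", category = c("a", "b"),
                      true_cell_fraction = c(0.1, 0))
  sc <- score_attribution(calls_df("s1", c("a", "b"), c(TRUE, FALSE)), truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)
  # all-negative truth with all-absent calls: sensitivity undefined
  truth0 <- data.frame(sample_id = "s1", category = c("a", "b"),
                       true_cell_fraction = c(0, 0))
  sc0 <- score_attribution(calls_df("s1", c("a", "b"), c(FALSE, FALSE)), truth0)
  expect_true(is.na(sc0$sensitivity))
  expect_equal(sc0$specificity, 1)
  expect_true(is.na(sc0$ppv))
})

test_that("mismatched samples and uncovered truth pairs are hard errors", {
  truth <- data.frame(sample_id = "s1", category = "a", true_cell_fraction = 0.1)
  expect_error(score_attribution(calls_df("s2", "a", TRUE), truth),
               "missing from truth")
  truth2 <- data.frame(sample_id = "s1", category = c("a", "b"),
                       true_cell_fraction = c(0.1, 0))
  expect_error(score_attribution(calls_df("s1", "a", TRUE), truth2),
               "without a call")
})

test_that("apportionment r matches the direct covariance formula", {
  truth <- data.frame(sample_id = rep(c("s1", "s2"), each = 3),
                      category = rep(c("a", "b", "c"), 2),
                      true_cell_fraction = c(0.2, 0.1, 0, 0.05, 0, 0.15))
  portions <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                         category = c("a", "b", "a", "c"),
                         portion = c(0.7, 0.3, 0.4, 0.6),
                         stringsAsFactors = FALSE)
  r <- score_apportionment(portions, truth)
  # brute-force oracle: build both vectors by hand and apply the definition
  pred <- c(0.7, 0.3, 0, 0.4, 0, 0.6)
  tru <- c(0.2 / 0.3, 0.1 / 0.3, 0, 0.05 / 0.2, 0, 0.15 / 0.2)
  r_oracle <- sum((pred - mean(pred)) * (tru - mean(tru))) /
    sqrt(sum((pred - mean(pred))^2) * sum((tru - mean(tru))^2))
  expect_equal(r, r_oracle)
  # identical predictions give r = 1; offsets preserve r = 1
  ident <- data.frame(sample_id = truth$sample_id, category = truth$category,
                      portion = tru, stringsAsFactors = FALSE)
  expect_equal(score_apportionment(ident, truth), 1)
  offset <- ident
  offset$portion <- offset$portion + 0.1
  expect_equal(score_apportionment(offset, truth), 1)
  # constant vector -> undefined
  truth_const <- data.frame(sample_id = c("s1", "s2", "s3"), category = "a",
                            true_cell_fraction = c(0.1, 0.1, 0.1))
  flat <- data.frame(sample_id = c("s1", "s2", "s3"), category = "a",
                     portion = c(1, 1, 1), stringsAsFactors = FALSE)
  expect_true(is.na(score_apportionment(flat, truth_const)))
})

test_that("calibration matches the closed-form normal-equations oracle", {
  pred <- c(0.01, 0.02, 0.05, 0.08, 0.10)
  tru <- c(0.04, 0.05, 0.18, 0.25, 0.36)
  fit <- calibrate_cell_fractions(pred, tru)
  # normal equations oracle
  slope_o <- sum((pred - mean(pred)) * (tru - mean(tru))) /
    sum((pred - mean(pred))^2)
  int_o <- mean(tru) - slope_o * mean(pred)
  resid <- tru - (int_o + slope_o * pred)
  r2_o <- 1 - sum(resid^2) / sum((tru - mean(tru))^2)
  expect_equal(fit$slope, slope_o)
  expect_equal(fit$intercept, int_o)
  expect_equal(fit$r_squared, r2_o)
  # exact scalings
  f3 <- calibrate_cell_fractions(pred, 3 * pred)
  expect_equal(f3$slope, 3)
  expect_equal(f3$intercept, 0)
  expect_equal(f3$r_squared, 1)
  expect_equal(calibrate_cell_fractions(pred, pred)$slope, 1)
  expect_error(calibrate_cell_fractions(rep(0.1, 5), pred), "constant")
})

test_that("the default grid enumerates 640 combinations; degenerate grids work", {
  grid <- default_parameter_grid()
  expect_identical(grid$n_combinations, 640L)
  expect_true(93 %in% grid$identities)
  expect_true(70 %in% grid$overlaps)
  expect_true(0 %in% grid$maskings)
  expect_true(0.01 %in% grid$lods)
  g1 <- parameter_grid(93, 70, 0, 0.01)
  expect_identical(g1$n_combinations, 1L)
  expect_error(parameter_grid(numeric(0), 70, 0, 0.01))
})

# small benchmark where catB's only signal is 90%-identity noise reads:
# identity >= 93 removes it, identity below keeps a false positive
grid_benchmark <- function() {
  set.seed(601)
  seqs <- c(a1 = random_dna(2000), b1 = random_dna(2000))
  db <- db_from_seqs(seqs, c(a1 = "catA", b1 = "catB"))
  mk_rec <- function(n, rname, nm, offset) {
    data.frame(qname = sprintf("%s_%d", rname, seq_len(n) + offset),
               flag = 0L, rname = rname,
               pos = as.integer(seq(1, 1800, length.out = n)),
               cigar = "150M", seq = strrep("A", 150), nm = nm,
               stringsAsFactors = FALSE)
  }
  sam <- write_sam_fixture(rbind(mk_rec(60, "a1", 0L, 0),
                                 mk_rec(40, "b1", 15L, 100)),
                           c(a1 = 2000L, b1 = 2000L))
  aln <- parse_alignments(sam, db)
  truth <- data.frame(sample_id = "bench", category = c("catA", "catB"),
                      true_cell_fraction = c(0.3, 0))
  samples <- list(list(sample_id = "bench", alignments = aln,
                       geq = estimate_geq(15000, ags_bp = 1000)))
  list(db = db, samples = samples, truth = truth)
}

test_that("grid ranking is deterministic and separates on identity", {
  bm <- grid_benchmark()
  grid <- parameter_grid(identities = c(85, 89, 93, 97), overlaps = c(50, 90),
                         maskings = c(0, 50), lods = c(0.01, 0.1))
  res <- run_parameter_grid(bm$samples, bm$db, grid, bm$truth)
  expect_identical(nrow(res), 32L)
  expect_identical(res$rank, 1:32)
  # noise reads sit at identity 90: only thresholds >= 93 avoid the catB
  # false positive, so every top-ranked (fp = 0) set has identity >= 93
  expect_true(all(res$min_identity[res$fp == 0] >= 93))
  expect_true(all(res$min_identity[res$fp > 0] < 93))
  # exhaustive re-scoring oracle: rank order matches a naive recompute
  naive <- list()
  for (i in seq_len(nrow(res))) {
    p <- res[i, ]
    filt <- filter_alignments(bm$samples[[1]]$alignments, p$min_identity,
                              p$min_overlap)
    d <- compute_depth(filt, bm$db, p$masking_percent, sample_id = "bench")
    cf <- cell_fractions(d, bm$db, bm$samples[[1]]$geq)
    rep <- sample_report(cf, lod_percent = p$lod_percent)
    sc <- score_attribution(as.data.frame(rep$calls), bm$truth)
    naive[[i]] <- c(tp = sc$tp, fp = sc$fp, fn = sc$fn, tn = sc$tn)
  }
  naive <- do.call(rbind, naive)
  expect_equal(unname(as.matrix(res[, c("tp", "fp", "fn", "tn")])),
               unname(naive))
})

test_that("grid results equal the naive loop and ranking keys are honored", {
  bm <- grid_benchmark()
  grid <- parameter_grid(identities = c(89, 93), overlaps = 70,
                         maskings = 0, lods = c(0.01, 0.1))
  res <- run_parameter_grid(bm$samples, bm$db, grid, bm$truth)
  expect_identical(nrow(res), 4L)
  # NPV first, then sensitivity, then specificity
  key <- order(-ifelse(is.na(res$npv), -Inf, res$npv),
               -ifelse(is.na(res$sensitivity), -Inf, res$sensitivity),
               -ifelse(is.na(res$specificity), -Inf, res$specificity))
  expect_identical(key, seq_len(4L))
})
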