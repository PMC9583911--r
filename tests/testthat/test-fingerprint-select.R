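# Hand-built abundance tables for selection-level tests.
fake_abundance <- function(rpkm) {
  structure(list(counts = round(rpkm), rpkm = rpkm,
                 library_sizes = stats::setNames(rep(1e6, ncol(rpkm)),
                                                 colnames(rpkm)),
                 contig_lengths = stats::setNames(rep(1000L, nrow(rpkm)),
                                                  rownames(rpkm)),
                 coverage = NULL),
            class = "abundance_table")
}

test_that("the abundance filter keeps contigs above a strict mean-RPKM floor", {
  rpkm <- rbind(c1 = c(0.004, 0.006, 5, 5),
                c2 = c(0.010, 0.010, 0, 0),
                c3 = c(0.012, 0.010, 0, 0))
  colnames(rpkm) <- c("p1", "p2", "n1", "n2")
  ab <- fake_abundance(rpkm)
  kept <- filter_contigs_by_abundance(ab, c("p1", "p2"), 0.01)
  expect_identical(kept, "c3")     # 0.005 dropped; 0.010 exactly dropped (>)
  expect_setequal(filter_contigs_by_abundance(ab, c("p1", "p2"), 0),
                  c("c1", "c2", "c3"))
  expect_error(filter_contigs_by_abundance(ab, c("n1", "n2"), 10),
               "no abundant contig")
})

test_that("rank AUC matches examples and the all-pairs oracle", {
  expect_equal(auc_of_contig(c(37.5, 100), c(0, 1)), 1.0)
  expect_equal(auc_of_contig(c(1, 3), c(2, 4)), 0.25)
  expect_equal(auc_of_contig(c(2, 2), c(2, 2)), 0.5)  # all ties
  expect_error(auc_of_contig(numeric(), 1), "non-empty")
  set.seed(41)
  for (i in 1:400) {
    pos <- round(stats::runif(sample(1:8, 1), 0, 4), 1)  # ties likely
    neg <- round(stats::runif(sample(1:8, 1), 0, 4), 1)
    expect_equal(auc_of_contig(pos, neg), oracle_auc(pos, neg))
  }
})

test_that("rank AUC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(42)
  pos <- stats::runif(20, 1, 3)
  neg <- stats::runif(30, 0, 2)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(20, 30)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_of_contig(pos, neg), ref)
})

test_that("the ROC grid scan finds the first closest-to-perfect threshold", {
  # first zero-distance grid point above the largest negative
  expect_equal(optimal_threshold(c(10, 20), c(0, 1), 0.001), 1.001)
  # separated data: sensitivity = specificity = 1 at the returned threshold
  set.seed(43)
  for (i in 1:20) {
    pos <- stats::runif(5, 2, 3)
    neg <- stats::runif(5, 0, 1)
    t <- optimal_threshold(pos, neg, 0.01)
    expect_equal(mean(pos >= t), 1)
    expect_equal(mean(neg < t), 1)
  }
  # indistinguishable groups and inverted groups degrade gracefully
  expect_equal(optimal_threshold(5, 5, 0.5), oracle_threshold(5, 5, 0.5))
  expect_message(t0 <- optimal_threshold(1, 5, 0.5), "degenerate")
  expect_equal(t0, 0)
  expect_error(optimal_threshold(1, 2, 0), "step")
})

test_that("the vectorized grid scan equals a naive exhaustive scan", {
  set.seed(44)
  for (i in 1:40) {
    pos <- round(stats::runif(sample(2:6, 1), 0, 3), 2)
    neg <- round(stats::runif(sample(2:6, 1), 0, 3), 2)
    expect_equal(optimal_threshold(pos, neg, 0.01),
                 oracle_threshold(pos, neg, 0.01))
  }
})

test_that("fingerprint selection ranks by CV AUC with stable tie-breaks", {
  set.seed(45)
  samples <- sprintf("s%02d", 1:12)
  pos_ids <- samples[1:4]
  # c_good separates perfectly; c_bad overlaps heavily
  rpkm <- rbind(c_good = c(stats::runif(4, 5, 6), stats::runif(8, 0, 1)),
                c_bad = c(stats::runif(4, 0, 2), stats::runif(8, 0, 2)))
  colnames(rpkm) <- samples
  ab <- fake_abundance(rpkm)
  contigs <- data.frame(contig_id = c("c_good", "c_bad"),
                        sequence = c(strrep("ACGT", 250), strrep("GGCA", 250)),
                        length = c(1000L, 1000L), individual_id = "A",
                        stringsAsFactors = FALSE)
  fp <- select_fingerprint(ab, contigs, pos_ids, cv_folds = 4, roc_step = 0.01,
                           seed = 7, min_rpkm = 0.01)
  expect_s3_class(fp, "fingerprint_marker")
  expect_equal(fp$contig_id, "c_good")
  expect_equal(fp$cv_auc_mean, 1.0)
  expect_equal(fp$rpkm_threshold, mean(fp$fold_thresholds))
  # threshold sits between the positive and negative RPKM ranges
  expect_lt(fp$rpkm_threshold, min(rpkm["c_good", pos_ids]))
  expect_gt(fp$rpkm_threshold, stats::median(rpkm["c_good", samples[5:12]]))
  # determinism and row-order invariance
  fp2 <- select_fingerprint(ab, contigs, pos_ids, cv_folds = 4,
                            roc_step = 0.01, seed = 7, min_rpkm = 0.01)
  expect_equal(fp2[c("contig_id", "rpkm_threshold", "cv_auc_mean")],
               fp[c("contig_id", "rpkm_threshold", "cv_auc_mean")])
  ab_flip <- fake_abundance(rpkm[c("c_bad", "c_good"), ])
  fp3 <- select_fingerprint(ab_flip, contigs[2:1, ], pos_ids, cv_folds = 4,
                            roc_step = 0.01, seed = 7, min_rpkm = 0.01)
  expect_equal(fp3$contig_id, "c_good")
})

test_that("AUC ties are broken toward the longer contig", {
  samples <- sprintf("s%02d", 1:8)
  rpkm <- rbind(c_short = rep(c(4, 0), c(4, 4)),
                c_long = rep(c(4, 0), c(4, 4)))
  colnames(rpkm) <- samples
  ab <- fake_abundance(rpkm)
  ab$contig_lengths <- stats::setNames(c(500L, 900L), rownames(rpkm))
  contigs <- data.frame(contig_id = c("c_short", "c_long"),
                        sequence = c(strrep("A", 500), strrep("C", 900)),
                        length = c(500L, 900L), individual_id = "A",
                        stringsAsFactors = FALSE)
  fp <- suppressWarnings(select_fingerprint(ab, contigs, samples[1:4],
                                            cv_folds = 4, roc_step = 0.01,
                                            seed = 1))
  expect_equal(fp$contig_id, "c_long")
})
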