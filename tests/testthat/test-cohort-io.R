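test_that("manifests round-trip through TSV and reject malformed input", {
  m <- synthetic_manifest(c(A = 2, B = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(m, path)
  m2 <- load_manifest(path)
  expect_equal(as.data.frame(m2), as.data.frame(m))

  bad <- as.data.frame(m)
  bad$sample_id[2] <- bad$sample_id[1]
  expect_error(as_cohort_manifest(bad), "A_x01")
  expect_error(as_cohort_manifest(bad[, -3]), "body_site")
})

test_that("QC removes low-depth samples with a strict cutoff", {
  m <- synthetic_manifest(c(A = 5), n_reads = c(100L, 1000L, 1000L, 1000L, 1000L))
  # median 1000, cutoff 100: strict "<" keeps the 100-read sample
  out <- qc_filter(m, min_read_fraction_of_median = 1 / 10)
  expect_equal(nrow(out), 5)
  expect_equal(nrow(attr(out, "removed")), 0)

  # the absolute floor: 99,999 reads falls below a 100,000 minimum
  m$n_reads <- c(99999L, rep(1000000L, 4))
  out <- qc_filter(m, absolute_min_reads = 100000)
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "removed")$sample_id, "A_x01")
  expect_equal(attr(out, "removed")$reason, "low_depth")
})

test_that("QC removes excluded body sites and is idempotent", {
  m <- synthetic_manifest(c(A = 3, B = 3))
  out <- qc_filter(m, excluded_sites = c("Ph", "Tn", "Tw"))
  expect_false(any(out$body_site == "Ph"))
  expect_true(all(attr(out, "removed")$reason == "excluded_site"))
  again <- qc_filter(out, excluded_sites = c("Ph", "Tn", "Tw"))
  expect_equal(again$sample_id, out$sample_id)
  expect_equal(nrow(attr(again, "removed")), 0)
  expect_error(qc_filter(m, excluded_sites = c("Fh", "Vf", "Ph")),
               "empty cohort")
})

test_that("the cohort split is stratified, deterministic and exhaustive", {
  m <- synthetic_manifest(c(A = 10, B = 4))
  plan <- split_cohort(m, 0.7, seed = 3)
  a_train <- sum(grepl("^A", plan$train_ids))
  expect_equal(a_train, 7)
  expect_equal(sum(grepl("^A", plan$test_ids)), 3)
  expect_identical(plan, split_cohort(m, 0.7, seed = 3))
  expect_false(identical(plan$train_ids, split_cohort(m, 0.7, 4)$train_ids))
  # partition property per individual
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  expect_setequal(c(plan$train_ids, plan$test_ids), m$sample_id)

  all_train <- split_cohort(m, 1.0, seed = 1)
  expect_length(all_train$test_ids, 0)
  expect_setequal(all_train$train_ids, m$sample_id)

  single <- synthetic_manifest(c(A = 1, B = 3))
  expect_warning(split_cohort(single, 0.7, 1), "single sample")
})

test_that("negative undersampling balances and never draws from the target", {
  m <- synthetic_manifest(c(T = 30, N01 = 30, N02 = 30, N03 = 30, N04 = 30,
                            N05 = 30, N06 = 30, N07 = 30, N08 = 30, N09 = 30,
                            N10 = 30, N11 = 20))
  plan <- split_cohort(m, 1.0, seed = 1)  # 30 positives, 320 negatives
  res <- undersample_negatives(m, plan, "T", ratio = 2.133, seed = 1)
  expect_length(res$positive_ids, 30)
  expect_length(res$negative_ids, 64)
  expect_false(any(grepl("^T_", res$negative_ids)))
  expect_false(anyDuplicated(res$negative_ids) > 0)
  # round-robin: 64 draws from 11 individuals covers every one of them
  expect_setequal(unique(sub("_x[0-9]+$", "", res$negative_ids)),
                  paste0("N", sprintf("%02d", 1:11)))

  m2 <- synthetic_manifest(c(A = 5, B = 100))
  plan2 <- split_cohort(m2, 1.0, seed = 1)
  expect_length(undersample_negatives(m2, plan2, "A", 1.0, 1)$negative_ids, 5)
  expect_warning(res3 <- undersample_negatives(m2, plan2, "B", 1.0, 1),
                 "available")
  expect_length(res3$negative_ids, 5)
  expect_error(undersample_negatives(m2, plan2, "A", 0), "positive")
})

test_that("FASTQ read counting and sequence loading work on real files", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "s1.fastq")
  writeLines(c("@r1", "ACGTACGTAA", "+", "IIIIIIIIII",
               "@r2", "TTTTTTTTTT", "+", "IIIIIIIIII"), fq)
  expect_equal(count_fastq_reads(fq), 2)
  m <- as_cohort_manifest(data.frame(
    sample_id = "s1", individual_id = "A", body_site = "Fh", timepoint = "T1",
    fastq_1 = fq, stringsAsFactors = FALSE))
  expect_equal(read_sample_seqs(m, "s1"), c("ACGTACGTAA", "TTTTTTTTTT"))
  expect_equal(validate_read_counts(m)$n_reads, 2L)

  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGTRCGTAA", "+", "IIIIIIIIII"), bad)
  mb <- as_cohort_manifest(data.frame(
    sample_id = "b", individual_id = "A", body_site = "Fh", timepoint = "T1",
    fastq_1 = bad, stringsAsFactors = FALSE))
  expect_error(read_sample_seqs(mb, "b"), "ACGTN")
})
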