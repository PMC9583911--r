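test_that("single-k-mer predictors score by averaged sensitivity/specificity", {
  labels <- rep(c("positive", "negative"), each = 5)
  # present in 4/5 positives, 1/5 negatives
  s <- score_kmer(c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0), labels)
  expect_equal(s[c("direction", "sensitivity", "specificity", "ass")],
               list(direction = "presence", sensitivity = 0.8,
                    specificity = 0.8, ass = 0.8))
  # perfect separators, both directions
  expect_equal(score_kmer(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), labels)$ass, 1.0)
  s2 <- score_kmer(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1), labels)
  expect_equal(s2$direction, "absence")
  expect_equal(s2$ass, 1.0)
  expect_error(score_kmer(c(1, 0), c("positive", "positive")), "non-empty")
})

test_that("scoring matches a brute-force confusion-matrix oracle", {
  set.seed(11)
  for (i in 1:300) {
    n_pos <- sample(2:8, 1)
    n_neg <- sample(2:8, 1)
    labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
    row <- stats::rbinom(n_pos + n_neg, 1, stats::runif(1, 0.2, 0.8))
    got <- score_kmer(row, labels)
    want <- oracle_score_kmer(row, labels)
    expect_equal(got$ass, want$ass)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$direction, want$direction)
  }
})

test_that("ASS is order-invariant and label-swap flips the direction", {
  set.seed(12)
  labels <- rep(c("positive", "negative"), c(6, 10))
  row <- stats::rbinom(16, 1, 0.5)
  base <- score_kmer(row, labels)
  perm <- sample(16)
  expect_equal(score_kmer(row[perm], labels[perm]), base)
  swapped <- score_kmer(row, ifelse(labels == "positive", "negative",
                                    "positive"))
  expect_equal(swapped$ass, base$ass)
  if (base$ass > 0.5)
    expect_false(swapped$direction == base$direction)
})

test_that("detection applies the inclusive ASS threshold deterministically", {
  kmers <- sort(random_kmer(3, 9))
  # ASS exactly 0.8 / 1.0 / 0.5 by construction (5 pos, 5 neg)
  tabs <- lapply(1:10, function(i) {
    present <- c(i %in% c(1, 2, 3, 4, 6), i <= 5, TRUE)
    fake_table(sprintf("s%02d", i), kmers[present], k = 9)
  })
  labels <- stats::setNames(rep(c("positive", "negative"), each = 5),
                            sprintf("s%02d", 1:10))
  m <- build_kmer_matrix(tabs, labels)
  rec8 <- detect_specific_kmers(m, specificity_config(ass_threshold = 0.8))
  expect_setequal(rec8$kmer, kmers[1:2])          # 0.8 included (>=)
  expect_equal(rec8$kmer[1], kmers[2])            # sorted by ASS descending
  rec9 <- detect_specific_kmers(m, specificity_config(ass_threshold = 0.9))
  expect_setequal(rec9$kmer, kmers[2])            # 0.8 now excluded

  # monotone in the threshold: raising theta1 gives a subset
  for (t in c(0.6, 0.7, 0.9, 1.0)) {
    expect_true(all(
      detect_specific_kmers(m, specificity_config(t))$kmer %in% rec8$kmer |
        t < 0.8))
  }
  empty <- build_kmer_matrix(list(fake_table("a", character(), k = 9),
                                  fake_table("b", character(), k = 9)),
                             c(a = "positive", b = "negative"))
  expect_warning(out <- detect_specific_kmers(empty), "empty")
  expect_equal(nrow(out), 0)
})

test_that("random labels yield (near-)no specific k-mers at theta1 = 0.9", {
  set.seed(13)
  kmers <- random_kmer(200, 31)
  tabs <- lapply(1:36, function(i)
    fake_table(sprintf("s%02d", i), kmers[stats::runif(200) < 0.5]))
  labels <- stats::setNames(
    sample(rep(c("positive", "negative"), c(6, 30))), sprintf("s%02d", 1:36))
  m <- filter_sparse(build_kmer_matrix(tabs, labels), 0.8)
  rec <- detect_specific_kmers(m, specificity_config(ass_threshold = 0.9))
  expect_lt(nrow(rec) / 200, 0.05)
})

test_that("cross-validated detection validates perfectly on separable data", {
  specific <- sort(random_kmer(5, 31))
  shared <- sort(random_kmer(20, 31))
  tabs <- lapply(1:18, function(i) {
    km <- if (i <= 6) c(specific, shared) else shared
    fake_table(sprintf("s%02d", i), km)
  })
  labels <- stats::setNames(rep(c("positive", "negative"), c(6, 12)),
                            sprintf("s%02d", 1:18))
  cfg <- specificity_config(ass_threshold = 0.8, cv_folds = 6, seed = 9)
  cv <- crossvalidate_specific_kmers(tabs, labels, cfg)
  expect_length(cv, 6)
  for (fold in cv) {
    expect_setequal(fold$detected$kmer, specific)
    expect_equal(fold$fraction_validated, 1.0)
    expect_true(all(fold$detected$ass_validation == 1.0))
  }
  cv2 <- crossvalidate_specific_kmers(tabs, labels, cfg)
  expect_identical(cv, cv2)  # same seed, same folds
  expect_error(crossvalidate_specific_kmers(
    tabs[5:18], labels[5:18], cfg), "positive")
})

test_that("grouped re-scoring reproduces training ASS on the training slice", {
  specific <- sort(random_kmer(4, 31))
  shared <- sort(random_kmer(10, 31))
  tabs <- lapply(1:12, function(i) {
    km <- if (i <= 4) c(specific, shared) else shared
    fake_table(sprintf("s%02d", i), km)
  })
  labels <- stats::setNames(rep(c("positive", "negative"), c(4, 8)),
                            sprintf("s%02d", 1:12))
  m <- build_kmer_matrix(tabs, labels)
  rec <- detect_specific_kmers(m, specificity_config(0.8))
  one_part <- stats::setNames(rep("train", 12), names(labels))
  ev <- evaluate_on_grouping(rec, tabs, labels, one_part)
  expect_equal(attr(ev, "per_record")[, "train"],
               stats::setNames(rec$ass, rec$kmer))
  expect_equal(ev$fraction_ass_ge_0.8, 1.0)

  # a partition lacking one group is skipped with a warning
  part <- stats::setNames(c(rep("b", 6), rep("a", 6)), names(labels))
  expect_warning(ev2 <- evaluate_on_grouping(rec, tabs, labels, part),
                 "lacks a group")
  expect_equal(ev2$partition, "b")
})
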