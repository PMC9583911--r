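test_that("Gini impurity and the branch-weighted index match closed forms", {
  expect_equal(gini(rep("A", 4)), 0)
  expect_equal(gini(c("A", "A", "A", "B", "B", "B")), 0.5)
  expect_equal(gini(rep(c("A", "B", "C", "D"), 2)), 0.75)
  for (K in 2:6) expect_equal(gini(seq_len(K)), 1 - 1 / K)
  expect_error(gini(character()), "empty")

  lab <- rep(c("A", "B"), each = 4)
  v <- c(5, 6, 7, 8, 0, 1, 2, 3)
  expect_equal(gini_index(lab, v, 4), 0)          # perfect isolation
  expect_equal(gini_index(lab, v, 100), gini(lab)) # split separates nothing
  expect_error(gini_index(lab, v, NA), "missing")
})

test_that("Gini computations match exhaustive enumeration on small multisets", {
  classes <- c("A", "B", "C")
  for (n in 1:6) {
    combos <- expand.grid(rep(list(classes), n), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      lab <- unlist(combos[r, ], use.names = FALSE)
      expect_equal(gini(lab), oracle_gini(lab))
      vals <- seq_len(n) %% 3
      for (thr in c(0.5, 1.5, 2.5))
        expect_equal(gini_index(lab, vals, thr),
                     oracle_gini_index(lab, vals, thr))
    }
  }
})

test_that("the decision tree isolates individuals greedily and deterministically", {
  samples <- sprintf("s%d", 1:9)
  labels <- stats::setNames(rep(c("A", "B", "C"), each = 3), samples)
  rpkm <- rbind(A = c(9, 9, 9, 0, 0, 0, 0, 0, 0),
                B = c(0, 0, 0, 7, 7, 7, 0, 0, 0),
                C = c(0, 0, 0, 0, 0, 0, 5, 5, 5))
  colnames(rpkm) <- samples
  thr <- c(A = 1, B = 1, C = 1)
  tree <- build_identity_tree(rpkm, labels, thr)
  # separable: every training sample reaches its own leaf
  ev <- evaluate_identifier(tree, rpkm, labels)
  expect_equal(ev$accuracy, 1.0)
  expect_true(all(diag(ev$confusion[1:3, ]) == 3))
  # determinism and invariance to attribute presentation order
  tree2 <- build_identity_tree(rpkm[c(3, 1, 2), ], labels, thr)
  expect_equal(vapply(tree$nodes, `[[`, "", "kind"),
               vapply(tree2$nodes, `[[`, "", "kind"))
  for (s in samples)
    expect_equal(identify_donor(tree2, rpkm[, s]), identify_donor(tree, rpkm[, s]))
  expect_error(build_identity_tree(rpkm[c(1, 1, 2), ], labels, thr),
               "duplicate")
})

test_that("weak fingerprints sink to deeper decision nodes", {
  samples <- sprintf("s%d", 1:6)
  labels <- stats::setNames(rep(c("A", "B", "C"), each = 2), samples)
  # A and B isolate perfectly; C's fingerprint fires on only one of its two
  rpkm <- rbind(A = c(9, 9, 0, 0, 0, 0),
                B = c(0, 0, 7, 7, 0, 0),
                C = c(0, 0, 0, 0, 5, 0))
  colnames(rpkm) <- samples
  tree <- build_identity_tree(rpkm, labels, c(A = 1, B = 1, C = 1))
  order_of <- vapply(tree$nodes[vapply(tree$nodes, `[[`, "", "kind") ==
                                  "decision"], `[[`, "", "individual")
  expect_equal(order_of[3], "C")  # the impure attribute is chosen last
  expect_equal(identify_donor(tree, c(A = 0, B = 0, C = 0)), "unlabeled")
  expect_equal(identify_donor(tree, c(A = 3, B = 0, C = 0)), "A")
  ev <- evaluate_identifier(tree, rpkm, labels)
  expect_equal(unname(ev$confusion["unlabeled", "C"]), 1)
})

test_that("identification handles thresholds, unlabeled and missing inputs", {
  rpkm <- rbind(A = c(9, 0), B = c(0, 7))
  colnames(rpkm) <- c("s1", "s2")
  labels <- c(s1 = "A", s2 = "B")
  tree <- build_identity_tree(rpkm, labels, c(A = 5, B = 5))
  expect_equal(identify_donor(tree, c(A = 9, B = 0)), "A")
  expect_equal(identify_donor(tree, c(A = 0, B = 0)), "unlabeled")
  # a trace far below threshold: still unlabeled
  expect_equal(identify_donor(tree, c(A = 2.2, B = 0)), "unlabeled")
  expect_error(identify_donor(tree, c(A = 1)), "B")

  ev <- evaluate_identifier(tree, cbind(rpkm, s3 = c(0, 0), s4 = c(9, 0)),
                            c(labels, s3 = "A", s4 = "A"))
  expect_equal(ev$accuracy, 0.75)  # one of four unlabeled counts as an error
})

test_that("identity trees serialize and round-trip", {
  rpkm <- rbind(A = c(9, 9, 0, 0), B = c(0, 0, 7, 7))
  colnames(rpkm) <- sprintf("s%d", 1:4)
  labels <- stats::setNames(rep(c("A", "B"), each = 2), colnames(rpkm))
  tree <- build_identity_tree(rpkm, labels, c(A = 1.25, B = 2.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_identity_tree(tree, path)
  tree2 <- read_identity_tree(path)
  expect_equal(tree2$individuals, tree$individuals)
  for (s in colnames(rpkm))
    expect_equal(identify_donor(tree2, rpkm[, s]),
                 identify_donor(tree, rpkm[, s]))
  expect_equal(identify_donor(tree2, c(A = 0, B = 0)), "unlabeled")
})
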