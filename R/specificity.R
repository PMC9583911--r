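#' Specificity-scan configuration
#'
#' @param ass_threshold primary ASS threshold (theta1, default 0.80): the
#'   minimum average of sensitivity and specificity for a k-mer to count as
#'   individual-specific. Must lie in \[0.5, 1\].
#' @param cv_folds number of cross-validation folds (default 6).
#' @param secondary_threshold validation-side ASS threshold used when
#'   re-scoring detected k-mers on held-out samples (default 0.8).
#' @param seed integer seed for fold assignment.
#' @return a `specificity_config` list.
#' @export
specificity_config <- function(ass_threshold = 0.8, cv_folds = 6L,
                               secondary_threshold = 0.8, seed = 1L) {
  if (ass_threshold < 0.5 || ass_threshold > 1)
    stop("ass_threshold must be in [0.5, 1]")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(ass_threshold = ass_threshold, cv_folds = as.integer(cv_folds),
                 secondary_threshold = secondary_threshold,
                 seed = as.integer(seed)),
            class = "specificity_config")
}

#' Score one k-mer as a single-feature logical predictor
#'
#' Two predictor directions are considered: presence of the k-mer predicts the
#' positive group, or absence predicts the positive group. Sensitivity and
#' specificity are computed for each and the direction with the larger ASS
#' (average of sensitivity and specificity) is returned; exact ties go to the
#' presence direction, since a fingerprint should be detectable in its donor.
#'
#' @param logical_row 0/1 (or logical) presence vector across samples.
#' @param labels matching vector of `"positive"`/`"negative"`.
#' @return list with `direction` (`"presence"` or `"absence"`),
#'   `sensitivity`, `specificity`, `ass`.
#' @export
score_kmer <- function(logical_row, labels) {
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) stop("both groups must be non-empty")
  present <- as.logical(logical_row)
  sens_p <- mean(present[pos])
  spec_p <- mean(!present[!pos])
  ass_p <- (sens_p + spec_p) / 2
  if (ass_p >= 0.5) {
    list(direction = "presence", sensitivity = sens_p, specificity = spec_p,
         ass = ass_p)
  } else {
    list(direction = "absence", sensitivity = 1 - sens_p,
         specificity = 1 - spec_p, ass = 1 - ass_p)
  }
}

# Vectorized ASS over all rows of a logical matrix. Returns a data.frame.
score_all_kmers <- function(logical, kmers, labels) {
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) stop("both groups must be non-empty")
  sens_p <- rowMeans(logical[, pos, drop = FALSE])
  spec_p <- 1 - rowMeans(logical[, !pos, drop = FALSE])
  ass_p <- (sens_p + spec_p) / 2
  presence <- ass_p >= 0.5
  data.frame(kmer = kmers,
             direction = ifelse(presence, "presence", "absence"),
             sensitivity = ifelse(presence, sens_p, 1 - sens_p),
             specificity = ifelse(presence, spec_p, 1 - spec_p),
             ass = pmax(ass_p, 1 - ass_p),
             stringsAsFactors = FALSE)
}

#' Detect individual-specific k-mers
#'
#' Scores every k-mer of a (sparse-filtered) union matrix as a one-feature
#' logical predictor and keeps those achieving `ASS >= ass_threshold`
#' (inclusive). The result is sorted by decreasing ASS, ties by k-mer, so the
#' scan is fully deterministic.
#'
#' @param matrix a `kmer_matrix`.
#' @param config a [specificity_config()].
#' @return data frame of records: `kmer`, `direction`, `sensitivity`,
#'   `specificity`, `ass`.
#' @export
detect_specific_kmers <- function(matrix, config = specificity_config()) {
  if (length(matrix$kmers) == 0) {
    warning("empty k-mer matrix; no specific k-mers")
    return(data.frame(kmer = character(), direction = character(),
                      sensitivity = numeric(), specificity = numeric(),
                      ass = numeric(), stringsAsFactors = FALSE))
  }
  rec <- score_all_kmers(matrix$logical, matrix$kmers, matrix$labels)
  rec <- rec[rec$ass >= config$ass_threshold, , drop = FALSE]
  rec <- rec[order(-rec$ass, rec$kmer), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# Presence (TRUE/FALSE) of `kmers` in each table of `tables`; k-mers x samples.
kmer_presence <- function(kmers, tables) {
  m <- vapply(tables, function(t) kmers %in% t$kmer, logical(length(kmers)))
  if (length(kmers) == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- vapply(tables, `[[`, "", "sample_id")
  m
}

# Re-score fixed-direction records on new samples given their presence matrix.
rescore_records <- function(records, presence, labels) {
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) stop("both groups must be non-empty")
  pres_pos <- rowMeans(presence[, pos, drop = FALSE])
  pres_neg <- rowMeans(presence[, !pos, drop = FALSE])
  ifelse(records$direction == "presence",
         (pres_pos + (1 - pres_neg)) / 2,
         ((1 - pres_pos) + pres_neg) / 2)
}

#' Cross-validated detection of individual-specific k-mers
#'
#' Splits the labeled samples into `cv_folds` stratified folds. In each fold
#' the k-mer matrix is rebuilt on the fold-training samples, sparse-filtered,
#' and scanned at `ass_threshold`; every detected k-mer is then re-scored (in
#' its fixed direction) on the fold-validation samples.
#'
#' @param tables list of per-sample `kmer_counts`.
#' @param labels named `"positive"`/`"negative"` vector over the samples.
#' @param config a [specificity_config()].
#' @param max_absent_fraction sparsity threshold applied per fold.
#' @return list of per-fold lists: `detected` (record data frame with an
#'   `ass_validation` column) and `fraction_validated` (share of detected
#'   k-mers with validation ASS at or above the secondary threshold).
#' @export
crossvalidate_specific_kmers <- function(tables, labels,
                                         config = specificity_config(),
                                         max_absent_fraction = 0.8) {
  ids <- vapply(tables, `[[`, "", "sample_id")
  labels <- labels[ids]
  pos_ids <- ids[labels == "positive"]
  neg_ids <- ids[labels == "negative"]
  if (length(pos_ids) < config$cv_folds)
    stop("need at least cv_folds positive samples (have ", length(pos_ids), ")")
  folds <- make_folds(pos_ids, neg_ids, config$cv_folds, config$seed)
  lapply(seq_len(config$cv_folds), function(f) {
    val_ids <- folds[[f]]
    if (!any(val_ids %in% pos_ids)) stop("fold without positive samples")
    train_tab <- tables[!(ids %in% val_ids)]
    val_tab <- tables[ids %in% val_ids]
    mat <- build_kmer_matrix(train_tab, labels)
    mat <- filter_sparse(mat, max_absent_fraction)
    rec <- detect_specific_kmers(mat, config)
    if (nrow(rec) == 0)
      return(list(detected = rec, fraction_validated = NA_real_))
    pres <- kmer_presence(rec$kmer, val_tab)
    rec$ass_validation <- rescore_records(rec, pres,
                                          labels[colnames(pres)])
    list(detected = rec,
         fraction_validated = mean(rec$ass_validation >=
                                     config$secondary_threshold))
  })
}

# Stratified fold assignment: shuffle each group, deal round-robin.
make_folds <- function(pos_ids, neg_ids, cv_folds, seed) {
  with_seed(seed, {
    pos_ids <- sample(pos_ids)
    neg_ids <- sample(neg_ids)
  })
  folds <- vector("list", cv_folds)
  for (i in seq_along(pos_ids)) {
    f <- ((i - 1L) %% cv_folds) + 1L
    folds[[f]] <- c(folds[[f]], pos_ids[i])
  }
  for (i in seq_along(neg_ids)) {
    f <- ((i - 1L) %% cv_folds) + 1L
    folds[[f]] <- c(folds[[f]], neg_ids[i])
  }
  folds
}

#' Evaluate detected k-mers on sample groupings
#'
#' Re-scores each record's fixed predictor direction on every partition of the
#' supplied samples (for example per timepoint, or per body-site stratum) and
#' summarizes, per partition, the fraction of records keeping ASS at or above
#' 0.8 and 0.9. This is the temporal-stability / body-site-independence check:
#' k-mers detected on one slice of the cohort should remain discriminative on
#' the others.
#'
#' @param records record data frame from [detect_specific_kmers()].
#' @param tables list of per-sample `kmer_counts` for the evaluation samples.
#' @param labels named `"positive"`/`"negative"` vector.
#' @param partition named factor/character vector assigning each sample to a
#'   partition (e.g. its timepoint).
#' @return data frame with one row per usable partition: `partition`, `n_records`,
#'   `fraction_ass_ge_0.8`, `fraction_ass_ge_0.9`, `mean_ass`; per-record ASS
#'   values attached as `attr(, "per_record")` (records x partitions matrix).
#' @export
evaluate_on_grouping <- function(records, tables, labels, partition) {
  if (nrow(records) == 0) stop("no records to evaluate")
  ids <- vapply(tables, `[[`, "", "sample_id")
  partition <- partition[ids]
  labels <- labels[ids]
  pres <- kmer_presence(records$kmer, tables)
  levels <- sort(unique(as.character(partition)))
  per_rec <- matrix(NA_real_, nrow(records), length(levels),
                    dimnames = list(records$kmer, levels))
  rows <- list()
  for (lv in levels) {
    in_part <- partition == lv
    lab <- labels[in_part]
    if (!any(lab == "positive") || !any(lab == "negative")) {
      warning("partition '", lv, "' lacks a group; skipped")
      next
    }
    ass <- rescore_records(records, pres[, in_part, drop = FALSE], lab)
    per_rec[, lv] <- ass
    rows[[lv]] <- data.frame(partition = lv, n_records = nrow(records),
                             fraction_ass_ge_0.8 = mean(ass >= 0.8),
                             fraction_ass_ge_0.9 = mean(ass >= 0.9),
                             mean_ass = mean(ass), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_record") <- per_rec
  out
}
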