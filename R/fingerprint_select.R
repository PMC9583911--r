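#' Filter candidate contigs by abundance
#'
#' Keeps contigs whose mean RPKM across the target individual's training
#' samples is strictly greater than `min_rpkm`: a fingerprint must be
#' reliably observable in its own donor.
#'
#' @param abundance an `abundance_table` over the candidate contigs.
#' @param positive_ids the individual's training sample_ids.
#' @param min_rpkm abundance floor (default 0.01).
#' @return character vector of surviving contig_ids.
#' @export
filter_contigs_by_abundance <- function(abundance, positive_ids,
                                        min_rpkm = 0.01) {
  rpkm <- abundance$rpkm[, positive_ids, drop = FALSE]
  keep <- rowMeans(rpkm) > min_rpkm
  if (!any(keep)) stop("no abundant contig for individual (all mean RPKM <= ",
                       min_rpkm, ")")
  rownames(rpkm)[keep]
}

#' Rank-based AUC of a single abundance feature
#'
#' `AUC = P(positive > negative) + P(tie)/2` over all positive/negative pairs
#' (the Mann-Whitney formulation), computed from midranks.
#'
#' @param positives RPKM values in the positive group.
#' @param negatives RPKM values in the negative group.
#' @return AUC in \[0, 1\].
#' @export
auc_of_contig <- function(positives, negatives) {
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both groups must be non-empty")
  r <- rank(c(positives, negatives))
  np <- length(positives)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(negatives))
}

#' ROC-optimal RPKM threshold on a fixed grid
#'
#' Scans candidate thresholds over `[0, max(observed)]` on a grid of spacing
#' `step`; a sample is called positive when its RPKM is at or above the
#' threshold. The grid point whose (sensitivity, 1 - specificity) lies closest
#' (Euclidean) to the perfect-performance corner (1, 0) is returned; ties go
#' to the smallest threshold.
#'
#' @param positives RPKM values in the positive group.
#' @param negatives RPKM values in the negative group.
#' @param step grid spacing (default 0.001).
#' @return the optimal threshold (a grid point).
#' @export
optimal_threshold <- function(positives, negatives, step = 0.001) {
  if (step <= 0) stop("step must be positive")
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both groups must be non-empty")
  if (all(positives <= min(negatives)))
    message("degenerate threshold scan: no positive exceeds every negative")
  hi <- max(positives, negatives)
  n_grid <- floor(hi / step) + 1
  sp <- sort(positives)
  sn <- sort(negatives)
  np <- length(sp)
  nn <- length(sn)
  best_d2 <- Inf
  best_t <- 0
  chunk <- 5e6
  for (start in seq(0, n_grid - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_grid - 1)
    t <- idx * step
    # count of values >= t via binary search on the sorted vectors
    sens <- (np - findInterval(t, sp, left.open = TRUE)) / np
    fpr <- (nn - findInterval(t, sn, left.open = TRUE)) / nn
    d2 <- (1 - sens)^2 + fpr^2
    j <- which.min(d2)  # which.min takes the first (smallest t) among ties
    if (d2[j] < best_d2 - 1e-15) {
      best_d2 <- d2[j]
      best_t <- t[j]
    }
  }
  best_t
}

#' Select one fingerprint contig per individual
#'
#' Ranks the abundance-filtered candidates by mean validation AUC over
#' stratified cross-validation folds of the training samples, breaking ties
#' toward the longer contig (a longer fingerprint is more unique in a larger
#' population) and then by contig_id. For the winning contig the ROC-optimal
#' RPKM threshold is computed on each fold's training portion and the fold
#' thresholds are averaged into the fingerprint's decision threshold.
#'
#' @param abundance an `abundance_table` over candidate contigs and all
#'   training samples.
#' @param contigs contig data frame for the candidates.
#' @param positive_ids the individual's training sample_ids.
#' @param cv_folds number of folds (default 6).
#' @param roc_step ROC grid spacing (default 0.001).
#' @param seed integer seed for fold assignment.
#' @param min_rpkm abundance floor passed to
#'   [filter_contigs_by_abundance()].
#' @return a `fingerprint_marker`: list with `individual_id`, `contig_id`,
#'   `sequence`, `length`, `rpkm_threshold`, `cv_auc_mean`, `fold_thresholds`,
#'   `fold_aucs`.
#' @export
select_fingerprint <- function(abundance, contigs, positive_ids,
                               cv_folds = 6L, roc_step = 0.001, seed = 1L,
                               min_rpkm = 0.01) {
  cand <- filter_contigs_by_abundance(abundance, positive_ids, min_rpkm)
  all_ids <- colnames(abundance$rpkm)
  neg_ids <- setdiff(all_ids, positive_ids)
  if (cv_folds > length(positive_ids)) {
    warning("cv_folds reduced to the number of positive samples (",
            length(positive_ids), ")")
    cv_folds <- length(positive_ids)
  }
  folds <- make_folds(sort(positive_ids), sort(neg_ids), cv_folds, seed)
  auc_mat <- matrix(NA_real_, length(cand), cv_folds,
                    dimnames = list(cand, NULL))
  for (f in seq_len(cv_folds)) {
    val <- folds[[f]]
    vp <- intersect(val, positive_ids)
    vn <- intersect(val, neg_ids)
    if (length(vp) == 0 || length(vn) == 0)
      stop("fold ", f, " lacks positives or negatives; reduce cv_folds")
    for (cid in cand)
      auc_mat[cid, f] <- auc_of_contig(abundance$rpkm[cid, vp],
                                       abundance$rpkm[cid, vn])
  }
  mean_auc <- rowMeans(auc_mat)
  len <- abundance$contig_lengths[cand]
  ord <- order(-mean_auc, -len, cand)
  winner <- cand[ord[1]]
  fold_thr <- vapply(seq_len(cv_folds), function(f) {
    tr <- setdiff(all_ids, folds[[f]])
    optimal_threshold(abundance$rpkm[winner, intersect(tr, positive_ids)],
                      abundance$rpkm[winner, intersect(tr, neg_ids)],
                      step = roc_step)
  }, 0)
  row <- match(winner, contigs$contig_id)
  structure(list(individual_id = contigs$individual_id[row],
                 contig_id = winner,
                 sequence = contigs$sequence[row],
                 length = contigs$length[row],
                 rpkm_threshold = mean(fold_thr),
                 cv_auc_mean = mean_auc[[winner]],
                 fold_thresholds = fold_thr,
                 fold_aucs = auc_mat[winner, ]),
            class = "fingerprint_marker")
}

#' Write a fingerprint panel
#'
#' Emits the fingerprints as FASTA plus a TSV sidecar (`individual_id`,
#' `contig_id`, `length`, `rpkm_threshold`, `cv_auc_mean`).
#'
#' @param fingerprints list of `fingerprint_marker`s.
#' @param fasta_path,tsv_path output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_fingerprints <- function(fingerprints, fasta_path, tsv_path) {
  df <- fingerprints_as_contigs(fingerprints)
  write_contigs_fasta(df, fasta_path)
  side <- data.frame(individual_id = df$individual_id,
                     contig_id = df$contig_id, length = df$length,
                     rpkm_threshold = vapply(fingerprints, `[[`, 0,
                                             "rpkm_threshold"),
                     cv_auc_mean = vapply(fingerprints, `[[`, 0, "cv_auc_mean"),
                     stringsAsFactors = FALSE)
  utils::write.table(side, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}

# Fingerprint panel as a contig data frame (for mapping/quantification).
fingerprints_as_contigs <- function(fingerprints) {
  data.frame(contig_id = vapply(fingerprints, `[[`, "", "contig_id"),
             sequence = vapply(fingerprints, `[[`, "", "sequence"),
             length = vapply(fingerprints, `[[`, 0L, "length"),
             individual_id = vapply(fingerprints, `[[`, "", "individual_id"),
             stringsAsFactors = FALSE)
}

#' @export
print.fingerprint_marker <- function(x, ...) {
  cat("Fingerprint for ", x$individual_id, ": ", x$contig_id, " (",
      x$length, " bp), RPKM threshold ", format(x$rpkm_threshold, digits = 5),
      ", CV AUC ", format(x$cv_auc_mean, digits = 4), "\n", sep = "")
  invisible(x)
}
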