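#' Pipeline configuration
#'
#' Every knob of the fingerprinting procedure in one validated object. The
#' defaults are the study conditions: 31-mers counted canonically with counts
#' below 3 dropped, sparsity filter at 80% absence in both groups, ASS
#' threshold 0.80, 6-fold cross-validation, read recruitment at 3 distinct
#' specific k-mers, assembly coverage floor 2 and minimum contig length
#' 100 bp, candidate-contig abundance floor 0.01 RPKM, ROC grid step 0.001,
#' 70/30 train/test split, and negative undersampling at 2 negatives per
#' positive.
#'
#' @param k k-mer length (odd, <= 31).
#' @param min_count minimum retained k-mer count per sample.
#' @param sparse_max_absent sparsity threshold for [filter_sparse()].
#' @param ass_threshold primary ASS threshold theta1 in \[0.5, 1\].
#' @param cv_folds cross-validation folds.
#' @param min_hits distinct specific k-mers required to recruit a read.
#' @param asm_coverage_floor de Bruijn node coverage floor.
#' @param min_contig_len minimum contig length (bp).
#' @param min_rpkm candidate-contig abundance floor (RPKM).
#' @param roc_step ROC threshold grid spacing.
#' @param train_fraction training fraction of the cohort split.
#' @param undersample_ratio negatives per positive in training.
#' @param min_shared_kmers read-to-contig mapping stringency; `NULL` (default)
#'   demands every read k-mer (end-to-end exact semantics).
#' @param excluded_sites body sites removed at QC.
#' @param min_read_fraction_of_median,absolute_min_reads QC depth cutoffs.
#' @param secondary_threshold validation-side ASS threshold.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(k = 31L, min_count = 3L, sparse_max_absent = 0.8,
                            ass_threshold = 0.8, cv_folds = 6L, min_hits = 3L,
                            asm_coverage_floor = 2L, min_contig_len = 100L,
                            min_rpkm = 0.01, roc_step = 0.001,
                            train_fraction = 0.7, undersample_ratio = 2.0,
                            min_shared_kmers = NULL,
                            excluded_sites = character(),
                            min_read_fraction_of_median = 0.1,
                            absolute_min_reads = 0,
                            secondary_threshold = 0.8, seed = 1L) {
  if (k %% 2 == 0 || k < 3 || k > 31) stop("k must be odd and in [3, 31]")
  if (ass_threshold < 0.5 || ass_threshold > 1)
    stop("ass_threshold must be in [0.5, 1]")
  if (sparse_max_absent < 0 || sparse_max_absent > 1)
    stop("sparse_max_absent must be in [0, 1]")
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]")
  if (undersample_ratio <= 0) stop("undersample_ratio must be positive")
  if (roc_step <= 0) stop("roc_step must be positive")
  if (min_hits < 1 || min_count < 1 || asm_coverage_floor < 1)
    stop("count thresholds must be >= 1")
  structure(list(k = as.integer(k), min_count = as.integer(min_count),
                 sparse_max_absent = sparse_max_absent,
                 ass_threshold = ass_threshold, cv_folds = as.integer(cv_folds),
                 min_hits = as.integer(min_hits),
                 asm_coverage_floor = as.integer(asm_coverage_floor),
                 min_contig_len = as.integer(min_contig_len),
                 min_rpkm = min_rpkm, roc_step = roc_step,
                 train_fraction = train_fraction,
                 undersample_ratio = undersample_ratio,
                 min_shared_kmers = min_shared_kmers,
                 excluded_sites = excluded_sites,
                 min_read_fraction_of_median = min_read_fraction_of_median,
                 absolute_min_reads = absolute_min_reads,
                 secondary_threshold = secondary_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `path` invisibly / the validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$min_shared_kmers <- if (is.null(x$min_shared_kmers)) "all"
                        else x$min_shared_kmers
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$min_shared_kmers, "all")) x$min_shared_kmers <- NULL
  if (is.null(x$excluded_sites)) x$excluded_sites <- character()
  do.call(pipeline_config, x)
}

#' Fit the microbial fingerprint identifier
#'
#' Runs the full procedure on a cohort: sample QC, stratified 70/30 split,
#' per-individual detection of specific k-mers on undersampled training data,
#' read recruitment and unitig assembly into candidate contigs, RPKM
#' quantification, cross-validated fingerprint selection with ROC-derived
#' thresholds, Gini decision-tree construction, and evaluation on the held-out
#' test samples.
#'
#' @param manifest a `cohort_manifest` (or path to a manifest TSV).
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, all artifacts (QC'd
#'   manifest, split, k-mer records, contigs, fingerprints, abundance tables,
#'   tree, evaluation, resolved config) are written there.
#' @param quiet suppress progress messages.
#' @return a fitted `fingerprint_fit` object; see [predict.fingerprint_fit()].
#' @export
fingerprint_fit <- function(manifest, config = pipeline_config(),
                            output_dir = NULL, quiet = FALSE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  say <- function(...) if (!quiet) message(...)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    say(msg)
  }

  note("QC: ", nrow(manifest), " samples in")
  manifest <- qc_filter(manifest, config$min_read_fraction_of_median,
                        config$absolute_min_reads, config$excluded_sites)
  removed <- attr(manifest, "removed")
  note("QC: ", nrow(manifest), " samples retained (", nrow(removed),
       " removed)")

  plan <- split_cohort(manifest, config$train_fraction, config$seed)
  note("split: ", length(plan$train_ids), " train / ", length(plan$test_ids),
       " test")

  all_ids <- manifest$sample_id
  seqs <- stats::setNames(lapply(all_ids, function(s)
    read_sample_seqs(manifest, s)), all_ids)
  tables <- stats::setNames(lapply(all_ids, function(s)
    count_canonical_kmers(seqs[[s]], config$k, config$min_count, s)), all_ids)

  individuals <- sort(unique(manifest$individual_id))
  ind_of <- stats::setNames(manifest$individual_id, manifest$sample_id)
  spec_cfg <- specificity_config(config$ass_threshold, config$cv_folds,
                                 config$secondary_threshold, config$seed)

  specific_kmers <- list()
  contigs <- list()
  fingerprints <- list()
  for (ind in individuals) {
    groups <- undersample_negatives(manifest, plan, ind,
                                    config$undersample_ratio, config$seed)
    labels <- stats::setNames(
      ifelse(ind_of[c(groups$positive_ids, groups$negative_ids)] == ind,
             "positive", "negative"),
      c(groups$positive_ids, groups$negative_ids))
    mat <- build_kmer_matrix(tables[names(labels)], labels)
    mat <- filter_sparse(mat, config$sparse_max_absent)
    rec <- detect_specific_kmers(mat, spec_cfg)
    specific_kmers[[ind]] <- rec
    note(ind, ": ", nrow(rec), " specific ", config$k, "-mers (",
         sum(rec$direction == "presence"), " presence-direction)")

    pos_reads <- unlist(seqs[groups$positive_ids], use.names = FALSE)
    recruited <- recruit_reads(rec, pos_reads, config$k, config$min_hits, ind)
    ctg <- assemble_unitigs(recruited, config$k, config$asm_coverage_floor,
                            config$min_contig_len, ind)
    if (nrow(ctg) == 0)
      stop("stage assemble failed for individual ", ind, ": no contigs")
    contigs[[ind]] <- ctg
    note(ind, ": ", length(recruited$reads), " reads recruited -> ",
         nrow(ctg), " candidate contigs")

    ab <- quantify_samples(ctg, seqs[plan$train_ids], config$k,
                           config$min_shared_kmers)
    fingerprints[[ind]] <- select_fingerprint(
      ab, ctg, positive_ids = plan$train_ids[ind_of[plan$train_ids] == ind],
      cv_folds = config$cv_folds, roc_step = config$roc_step,
      seed = config$seed, min_rpkm = config$min_rpkm)
    note(ind, ": fingerprint ", fingerprints[[ind]]$contig_id, " (",
         fingerprints[[ind]]$length, " bp), CV AUC ",
         format(fingerprints[[ind]]$cv_auc_mean, digits = 4),
         ", threshold ",
         format(fingerprints[[ind]]$rpkm_threshold, digits = 5))
  }

  panel <- fingerprints_as_contigs(fingerprints)
  ab_train <- quantify_samples(panel, seqs[plan$train_ids], config$k,
                               config$min_shared_kmers)
  ab_test <- quantify_samples(panel, seqs[plan$test_ids], config$k,
                              config$min_shared_kmers)
  feat <- function(ab) {
    m <- ab$rpkm
    rownames(m) <- panel$individual_id[match(rownames(m), panel$contig_id)]
    m
  }
  thresholds <- stats::setNames(
    vapply(fingerprints, `[[`, 0, "rpkm_threshold"),
    vapply(fingerprints, `[[`, "", "individual_id"))
  tree <- build_identity_tree(feat(ab_train), ind_of, thresholds)
  evaluation <- evaluate_identifier(tree, feat(ab_test), ind_of)
  note("held-out identification accuracy: ",
       format(evaluation$accuracy, digits = 4), " on ",
       length(plan$test_ids), " samples")

  fit <- structure(list(config = config, manifest = manifest,
                        removed = removed, split = plan,
                        specific_kmers = specific_kmers, contigs = contigs,
                        fingerprints = fingerprints, panel = panel,
                        thresholds = thresholds, tree = tree,
                        train_rpkm = feat(ab_train), test_rpkm = feat(ab_test),
                        evaluation = evaluation, log = log),
                   class = "fingerprint_fit")
  if (!is.null(output_dir)) write_fit_artifacts(fit, output_dir)
  fit
}

#' @rdname fingerprint_fit
#' @export
run_pipeline <- fingerprint_fit

write_fit_artifacts <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(fit$config, file.path(dir, "config.yaml"))
  write_manifest(fit$manifest, file.path(dir, "manifest_qc.tsv"))
  utils::write.table(fit$removed, file.path(dir, "removed_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  split_df <- data.frame(
    sample_id = c(fit$split$train_ids, fit$split$test_ids),
    role = rep(c("train", "test"), c(length(fit$split$train_ids),
                                     length(fit$split$test_ids))),
    stringsAsFactors = FALSE)
  utils::write.table(split_df, file.path(dir, "split.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "kmers"), showWarnings = FALSE)
  for (ind in names(fit$specific_kmers))
    utils::write.table(fit$specific_kmers[[ind]],
                       file.path(dir, "kmers", paste0(ind, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "contigs"), showWarnings = FALSE)
  for (ind in names(fit$contigs))
    write_contigs_fasta(fit$contigs[[ind]],
                        file.path(dir, "contigs", paste0(ind, ".fasta")))
  write_fingerprints(fit$fingerprints, file.path(dir, "fingerprints.fasta"),
                     file.path(dir, "fingerprints.tsv"))
  utils::write.table(data.frame(individual_id = rownames(fit$train_rpkm),
                                fit$train_rpkm, check.names = FALSE),
                     file.path(dir, "rpkm_train.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(individual_id = rownames(fit$test_rpkm),
                                fit$test_rpkm, check.names = FALSE),
                     file.path(dir, "rpkm_test.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_identity_tree(fit$tree, file.path(dir, "tree.tsv"))
  utils::write.table(as.data.frame.matrix(fit$evaluation$confusion),
                     file.path(dir, "confusion.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(fit$evaluation$per_individual,
                     file.path(dir, "per_individual.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(fit$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Identify donors of new samples with a fitted identifier
#'
#' @param object a `fingerprint_fit`.
#' @param newdata FASTQ path(s) (one sample each), a named list of read
#'   vectors, or a fingerprint x sample RPKM matrix.
#' @param type `"label"` (default) for donor calls, `"rpkm"` for the feature
#'   matrix.
#' @param ... unused.
#' @return named character vector of individual_ids / `"unlabeled"`, or the
#'   RPKM matrix.
#' @export
predict.fingerprint_fit <- function(object, newdata, type = c("label", "rpkm"),
                                    ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) {
    rpkm <- newdata
  } else {
    if (is.character(newdata)) {
      nm <- if (!is.null(names(newdata))) names(newdata)
            else sub("\\.(fastq|fq)(\\.gz)?$", "", basename(newdata))
      newdata <- stats::setNames(lapply(newdata, function(p)
        as.character(Biostrings::readDNAStringSet(p, format = "fastq"))), nm)
    }
    ab <- quantify_samples(object$panel, newdata, object$config$k,
                           object$config$min_shared_kmers)
    rpkm <- ab$rpkm
    rownames(rpkm) <- object$panel$individual_id[
      match(rownames(rpkm), object$panel$contig_id)]
  }
  if (type == "rpkm") return(rpkm)
  vapply(colnames(rpkm), function(s) identify_donor(object$tree, rpkm[, s]), "")
}

#' @export
print.fingerprint_fit <- function(x, ...) {
  cat("Microbial fingerprint identifier\n")
  cat("  cohort: ", nrow(x$manifest), " samples, ",
      length(x$fingerprints), " individuals\n", sep = "")
  cat("  fingerprints: ",
      paste(sprintf("%s (%d bp)",
                    vapply(x$fingerprints, `[[`, "", "contig_id"),
                    vapply(x$fingerprints, `[[`, 0L, "length")),
            collapse = ", "), "\n", sep = "")
  cat("  held-out accuracy: ", format(x$evaluation$accuracy, digits = 4),
      " on ", length(x$split$test_ids), " samples\n", sep = "")
  invisible(x)
}

#' @method summary fingerprint_fit
#' @export
summary.fingerprint_fit <- function(object, ...) {
  cat("Microbial fingerprint identifier -- summary\n\n")
  df <- data.frame(
    individual = vapply(object$fingerprints, `[[`, "", "individual_id"),
    n_specific_kmers = vapply(object$specific_kmers, nrow, 0L),
    n_contigs = vapply(object$contigs, nrow, 0L),
    fingerprint = vapply(object$fingerprints, `[[`, "", "contig_id"),
    length_bp = vapply(object$fingerprints, `[[`, 0L, "length"),
    cv_auc = round(vapply(object$fingerprints, `[[`, 0, "cv_auc_mean"), 4),
    rpkm_threshold = round(vapply(object$fingerprints, `[[`, 0,
                                  "rpkm_threshold"), 4),
    row.names = NULL)
  print(df)
  cat("\nDecision tree:\n")
  print(object$tree)
  cat("\nHeld-out confusion matrix (rows predicted, columns true):\n")
  print(object$evaluation$confusion)
  cat("\nAccuracy: ", format(object$evaluation$accuracy, digits = 4), "\n",
      sep = "")
  invisible(df)
}

#' RPKM decision thresholds of the fitted fingerprints
#'
#' @param object a `fingerprint_fit`.
#' @param ... unused.
#' @return named numeric vector of per-individual fingerprint thresholds.
#' @method coef fingerprint_fit
#' @export
coef.fingerprint_fit <- function(object, ...) object$thresholds

#' Fingerprint RPKM heat map of a fitted identifier
#'
#' Displays `log10(RPKM + 1)` of every fingerprint across the training
#' samples, samples grouped by individual -- the block-diagonal pattern is the
#' identifiability signal the tree exploits.
#'
#' @param x a `fingerprint_fit`.
#' @param which `"train"` or `"test"` samples.
#' @param ... passed to [graphics::image()].
#' @method plot fingerprint_fit
#' @export
plot.fingerprint_fit <- function(x, which = c("train", "test"), ...) {
  which <- match.arg(which)
  m <- if (which == "train") x$train_rpkm else x$test_rpkm
  ord <- order(x$manifest$individual_id[match(colnames(m),
                                              x$manifest$sample_id)])
  m <- log10(m[, ord, drop = FALSE] + 1)
  graphics::image(t(m), axes = FALSE,
                  xlab = paste(which, "samples (grouped by individual)"),
                  ylab = "fingerprint", ...)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.7)
  invisible(m)
}

#' Re-run a single pipeline stage from serialized artifacts
#'
#' Each stage reads its inputs from `dir` (as written by [fingerprint_fit()]
#' with `output_dir`, or by earlier stages) and writes its outputs back, so a
#' run can be reproduced or resumed piecewise. Valid stages:
#' `simulate`, `qc`, `split`, `detect`, `assemble`, `quantify`, `select`,
#' `tree`, `evaluate`, `identify`, `run-all`.
#'
#' @param stage stage name.
#' @param dir run directory.
#' @param config a [pipeline_config()]; read from `dir/config.yaml` when NULL.
#' @param ... stage-specific arguments (`spec` for simulate; `fastq` for
#'   identify).
#' @return stage-dependent value.
#' @export
run_stage <- function(stage, dir, config = NULL, ...) {
  stages <- c("simulate", "qc", "split", "detect", "assemble", "quantify",
              "select", "tree", "evaluate", "identify", "run-all")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(stages, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  if (is.null(config)) {
    config <- if (file.exists(cfg_path)) read_pipeline_config(cfg_path)
              else pipeline_config()
  }
  write_pipeline_config(config, cfg_path)
  need <- function(path) {
    if (!file.exists(path)) stop("missing upstream artifact: ", path)
    path
  }
  switch(stage,
    "simulate" = {
      args <- list(...)
      spec <- if (is.null(args$spec)) cohort_spec(seed = config$seed)
              else args$spec
      simulate_cohort(spec, dir = file.path(dir, "cohort"))
    },
    "qc" = {
      manifest <- load_manifest(need(file.path(dir, "cohort", "manifest.tsv")))
      out <- qc_filter(manifest, config$min_read_fraction_of_median,
                       config$absolute_min_reads, config$excluded_sites)
      write_manifest(out, file.path(dir, "manifest_qc.tsv"))
      utils::write.table(attr(out, "removed"),
                         file.path(dir, "removed_samples.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out
    },
    "run-all" = {
      manifest <- load_manifest(need(file.path(dir, "cohort", "manifest.tsv")))
      fingerprint_fit(manifest, config, output_dir = dir)
    },
    "identify" = {
      args <- list(...)
      if (is.null(args$fastq)) stop("identify needs a fastq= argument")
      tree <- read_identity_tree(need(file.path(dir, "tree.tsv")))
      panel <- read_contigs_fasta(need(file.path(dir, "fingerprints.fasta")))
      reads <- as.character(Biostrings::readDNAStringSet(args$fastq,
                                                         format = "fastq"))
      ab <- quantify_samples(panel, list(sample = reads), config$k,
                             config$min_shared_kmers)
      rpkm <- stats::setNames(ab$rpkm[, 1],
                              panel$individual_id[match(rownames(ab$rpkm),
                                                        panel$contig_id)])
      identify_donor(tree, rpkm)
    },
    run_stage_inner(stage, dir, config)
  )
}

# qc/split/detect/assemble/quantify/select/tree/evaluate working from disk.
run_stage_inner <- function(stage, dir, config) {
  need <- function(path) {
    if (!file.exists(path)) stop("missing upstream artifact: ", path)
    path
  }
  manifest <- load_manifest(need(file.path(dir, "manifest_qc.tsv")))
  if (stage == "split") {
    plan <- split_cohort(manifest, config$train_fraction, config$seed)
    df <- data.frame(sample_id = c(plan$train_ids, plan$test_ids),
                     role = rep(c("train", "test"),
                                c(length(plan$train_ids),
                                  length(plan$test_ids))))
    utils::write.table(df, file.path(dir, "split.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(plan)
  }
  sp <- utils::read.delim(need(file.path(dir, "split.tsv")),
                          stringsAsFactors = FALSE)
  plan <- structure(list(train_ids = sort(sp$sample_id[sp$role == "train"]),
                         test_ids = sort(sp$sample_id[sp$role == "test"]),
                         seed = config$seed,
                         train_fraction = config$train_fraction),
                    class = "split_plan")
  ind_of <- stats::setNames(manifest$individual_id, manifest$sample_id)
  individuals <- sort(unique(manifest$individual_id))
  read_seqs <- function(ids) stats::setNames(
    lapply(ids, function(s) read_sample_seqs(manifest, s)), ids)

  if (stage == "detect") {
    seqs <- read_seqs(manifest$sample_id)
    tables <- stats::setNames(lapply(manifest$sample_id, function(s)
      count_canonical_kmers(seqs[[s]], config$k, config$min_count, s)),
      manifest$sample_id)
    dir.create(file.path(dir, "kmers"), showWarnings = FALSE)
    spec_cfg <- specificity_config(config$ass_threshold, config$cv_folds,
                                   config$secondary_threshold, config$seed)
    out <- list()
    for (ind in individuals) {
      groups <- undersample_negatives(manifest, plan, ind,
                                      config$undersample_ratio, config$seed)
      ids <- c(groups$positive_ids, groups$negative_ids)
      labels <- stats::setNames(ifelse(ind_of[ids] == ind, "positive",
                                       "negative"), ids)
      mat <- filter_sparse(build_kmer_matrix(tables[ids], labels),
                           config$sparse_max_absent)
      rec <- detect_specific_kmers(mat, spec_cfg)
      utils::write.table(rec, file.path(dir, "kmers", paste0(ind, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[ind]] <- rec
    }
    return(out)
  }
  if (stage == "assemble") {
    dir.create(file.path(dir, "contigs"), showWarnings = FALSE)
    out <- list()
    for (ind in individuals) {
      rec <- utils::read.delim(need(file.path(dir, "kmers",
                                              paste0(ind, ".tsv"))),
                               stringsAsFactors = FALSE)
      pos_ids <- plan$train_ids[ind_of[plan$train_ids] == ind]
      reads <- unlist(read_seqs(pos_ids), use.names = FALSE)
      recruited <- recruit_reads(rec, reads, config$k, config$min_hits, ind)
      ctg <- assemble_unitigs(recruited, config$k, config$asm_coverage_floor,
                              config$min_contig_len, ind)
      write_contigs_fasta(ctg, file.path(dir, "contigs", paste0(ind, ".fasta")))
      out[[ind]] <- ctg
    }
    return(out)
  }
  if (stage %in% c("quantify", "select")) {
    out <- list()
    seqs <- read_seqs(plan$train_ids)
    for (ind in individuals) {
      ctg <- read_contigs_fasta(need(file.path(dir, "contigs",
                                               paste0(ind, ".fasta"))))
      ab <- quantify_samples(ctg, seqs, config$k, config$min_shared_kmers)
      if (stage == "quantify") {
        utils::write.table(
          data.frame(contig_id = rownames(ab$rpkm), ab$rpkm,
                     check.names = FALSE),
          file.path(dir, paste0("rpkm_candidates_", ind, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        out[[ind]] <- ab
      } else {
        out[[ind]] <- select_fingerprint(
          ab, ctg, positive_ids = plan$train_ids[ind_of[plan$train_ids] == ind],
          cv_folds = config$cv_folds, roc_step = config$roc_step,
          seed = config$seed, min_rpkm = config$min_rpkm)
      }
    }
    if (stage == "select")
      write_fingerprints(out, file.path(dir, "fingerprints.fasta"),
                         file.path(dir, "fingerprints.tsv"))
    return(out)
  }
  # tree / evaluate share the fingerprint panel
  panel <- read_contigs_fasta(need(file.path(dir, "fingerprints.fasta")))
  side <- utils::read.delim(need(file.path(dir, "fingerprints.tsv")),
                            stringsAsFactors = FALSE)
  thresholds <- stats::setNames(side$rpkm_threshold, side$individual_id)
  feat <- function(ids) {
    ab <- quantify_samples(panel, read_seqs(ids), config$k,
                           config$min_shared_kmers)
    m <- ab$rpkm
    rownames(m) <- panel$individual_id[match(rownames(m), panel$contig_id)]
    m
  }
  if (stage == "tree") {
    tree <- build_identity_tree(feat(plan$train_ids), ind_of, thresholds)
    write_identity_tree(tree, file.path(dir, "tree.tsv"))
    return(tree)
  }
  # evaluate
  tree <- read_identity_tree(need(file.path(dir, "tree.tsv")))
  ev <- evaluate_identifier(tree, feat(plan$test_ids), ind_of)
  utils::write.table(as.data.frame.matrix(ev$confusion),
                     file.path(dir, "confusion.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(ev$per_individual,
                     file.path(dir, "per_individual.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ev
}
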