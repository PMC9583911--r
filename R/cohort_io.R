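#' Read a cohort manifest
#'
#' A manifest is a tab-separated table with one row per metagenomic sample and
#' header columns `sample_id`, `individual_id`, `body_site`, `timepoint`,
#' `fastq_1` and optionally `fastq_2` (paired reads) and `n_reads` (cached
#' read counts). Relative FASTQ paths are resolved against the manifest's
#' directory.
#'
#' @param path path to a TSV manifest.
#' @param check_files verify that the referenced FASTQ files exist.
#' @return a `cohort_manifest`: a data frame of validated sample records.
#' @export
load_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  as_cohort_manifest(df, base_dir = dirname(path), check_files = check_files)
}

#' Build a cohort manifest from a data frame
#'
#' @param df data frame with the manifest columns (see [load_manifest()]).
#' @param base_dir directory against which relative FASTQ paths are resolved.
#' @param check_files verify that referenced FASTQ files exist.
#' @return a `cohort_manifest`.
#' @export
as_cohort_manifest <- function(df, base_dir = ".", check_files = FALSE) {
  required <- c("sample_id", "individual_id", "body_site", "timepoint", "fastq_1")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0)
    stop("duplicate sample_id in manifest: ", paste(unique(dup), collapse = ", "))
  if (!"fastq_2" %in% names(df)) df$fastq_2 <- NA_character_
  df$fastq_2[!is.na(df$fastq_2) & !nzchar(df$fastq_2)] <- NA_character_
  if ("n_reads" %in% names(df)) {
    df$n_reads <- suppressWarnings(as.integer(df$n_reads))
  } else {
    df$n_reads <- NA_integer_
  }
  resolve <- function(p) ifelse(is.na(p) | grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base_dir, p))
  df$fastq_1 <- resolve(df$fastq_1)
  df$fastq_2 <- resolve(df$fastq_2)
  if (check_files) {
    paths <- c(df$fastq_1, df$fastq_2[!is.na(df$fastq_2)])
    bad <- paths[!file.exists(paths)]
    if (length(bad) > 0) {
      row <- df$sample_id[match(bad[1], df$fastq_1)]
      if (is.na(row)) row <- df$sample_id[match(bad[1], df$fastq_2)]
      stop("unreadable read file for sample ", row, ": ", bad[1])
    }
  }
  keep <- c("sample_id", "individual_id", "body_site", "timepoint",
            "fastq_1", "fastq_2", "n_reads")
  out <- df[, keep]
  rownames(out) <- NULL
  class(out) <- c("cohort_manifest", "data.frame")
  out
}

#' Write a cohort manifest to TSV
#'
#' @param manifest a `cohort_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Count reads in a FASTQ file
#'
#' @param path FASTQ file, plain or gzip.
#' @return integer number of records.
#' @export
count_fastq_reads <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 400000L)
    n <- n + length(chunk)
    if (length(chunk) < 400000L) break
  }
  if (n %% 4L != 0L) stop("truncated FASTQ (line count not divisible by 4): ", path)
  n %/% 4L
}

#' Read the sequences of a sample's FASTQ file(s)
#'
#' Paired files are concatenated (each mate counts as one read). Sequences
#' containing characters outside `ACGTN` are rejected.
#'
#' @param manifest a `cohort_manifest`.
#' @param sample_id sample to read.
#' @return character vector of read sequences.
#' @export
read_sample_seqs <- function(manifest, sample_id) {
  row <- manifest[manifest$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown sample_id: ", sample_id)
  paths <- c(row$fastq_1, row$fastq_2)
  paths <- paths[!is.na(paths)]
  seqs <- unlist(lapply(paths, function(p) {
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  }), use.names = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sample ", sample_id, ": ", sum(bad),
         " read(s) contain characters outside ACGTN")
  seqs
}

#' Fill in missing read counts
#'
#' @param manifest a `cohort_manifest`.
#' @return the manifest with `n_reads` populated (paired mates counted
#'   individually; paired files must agree in record count).
#' @export
validate_read_counts <- function(manifest) {
  for (i in seq_len(nrow(manifest))) {
    if (!is.na(manifest$n_reads[i])) next
    n1 <- count_fastq_reads(manifest$fastq_1[i])
    if (!is.na(manifest$fastq_2[i])) {
      n2 <- count_fastq_reads(manifest$fastq_2[i])
      if (n1 != n2)
        stop("sample ", manifest$sample_id[i],
             ": paired files have unequal read counts (", n1, " vs ", n2, ")")
      n1 <- n1 + n2
    }
    manifest$n_reads[i] <- n1
  }
  manifest
}

#' Sample-level quality filter
#'
#' Removes samples whose read count falls strictly below
#' `max(median(n_reads) * min_read_fraction_of_median, absolute_min_reads)` --
#' the extremely-low-depth rule -- and all samples from excluded body sites
#' (sites strongly shaped by habits and environment rather than the host).
#'
#' @param manifest a `cohort_manifest` with `n_reads` available (filled via
#'   [validate_read_counts()] otherwise).
#' @param min_read_fraction_of_median depth cutoff as a fraction of the cohort
#'   median read count (default 1/10).
#' @param absolute_min_reads absolute read-count floor (default 0).
#' @param excluded_sites character vector of `body_site` codes to drop.
#' @return filtered `cohort_manifest`; the removed samples and their reasons
#'   are attached as `attr(, "removed")` (a data frame `sample_id`, `reason`).
#' @export
qc_filter <- function(manifest, min_read_fraction_of_median = 0.1,
                      absolute_min_reads = 0, excluded_sites = character()) {
  if (anyNA(manifest$n_reads)) manifest <- validate_read_counts(manifest)
  med <- stats::median(manifest$n_reads)
  cutoff <- max(med * min_read_fraction_of_median, absolute_min_reads)
  low <- manifest$n_reads < cutoff
  site <- manifest$body_site %in% excluded_sites
  reason <- ifelse(low & site, "low_depth;excluded_site",
                   ifelse(low, "low_depth", ifelse(site, "excluded_site", NA)))
  removed <- data.frame(sample_id = manifest$sample_id[low | site],
                        reason = reason[low | site],
                        stringsAsFactors = FALSE)
  out <- manifest[!(low | site), , drop = FALSE]
  if (nrow(out) == 0) stop("empty cohort after QC")
  rownames(out) <- NULL
  class(out) <- c("cohort_manifest", "data.frame")
  attr(out, "removed") <- removed
  out
}

#' Stratified train/test split
#'
#' Splits the cohort into training and testing samples, stratified by
#' individual, at the given training fraction (rounding toward train). An
#' individual with a single sample is assigned to train with a warning.
#'
#' @param manifest a `cohort_manifest`.
#' @param train_fraction fraction of each individual's samples used for
#'   training (default 0.7).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return a `split_plan`: list with `train_ids`, `test_ids`, `seed`,
#'   `train_fraction`.
#' @export
split_cohort <- function(manifest, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]")
  train_ids <- character()
  test_ids <- character()
  with_seed(seed, {
    for (ind in sort(unique(manifest$individual_id))) {
      ids <- manifest$sample_id[manifest$individual_id == ind]
      if (length(ids) == 1) {
        warning("individual ", ind, " has a single sample; assigned to train")
        train_ids <- c(train_ids, ids)
        next
      }
      n_train <- min(length(ids), ceiling(length(ids) * train_fraction))
      picked <- sample(ids, n_train)
      train_ids <- c(train_ids, picked)
      test_ids <- c(test_ids, setdiff(ids, picked))
    }
  })
  structure(list(train_ids = sort(train_ids), test_ids = sort(test_ids),
                 seed = as.integer(seed), train_fraction = train_fraction),
            class = "split_plan")
}

#' Undersample the negative class for one target individual
#'
#' Training samples of all other individuals form the negative pool; a
#' balanced subset of size `round(ratio * n_positives)` (capped by
#' availability) is drawn without replacement, round-robin across the other
#' individuals so that no single individual dominates the negatives.
#'
#' @param manifest a `cohort_manifest`.
#' @param plan a `split_plan` from [split_cohort()].
#' @param target_individual the positive individual.
#' @param ratio negatives per positive (default 2).
#' @param seed integer seed.
#' @return list with `positive_ids` and `negative_ids`.
#' @export
undersample_negatives <- function(manifest, plan, target_individual,
                                  ratio = 2, seed = 1L) {
  if (ratio <= 0) stop("ratio must be positive")
  train <- manifest[manifest$sample_id %in% plan$train_ids, , drop = FALSE]
  pos <- train$sample_id[train$individual_id == target_individual]
  if (length(pos) == 0)
    stop("target individual ", target_individual, " has no training samples")
  pools <- split(train$sample_id[train$individual_id != target_individual],
                 train$individual_id[train$individual_id != target_individual])
  n_avail <- sum(lengths(pools))
  n_want <- round(ratio * length(pos))
  if (n_want > n_avail) {
    warning("only ", n_avail, " negatives available (requested ", n_want, ")")
    n_want <- n_avail
  }
  neg <- character()
  with_seed(seed, {
    pools <- lapply(pools[sort(names(pools))], sample)
    round_i <- 1L
    while (length(neg) < n_want) {
      for (ind in names(pools)) {
        if (length(neg) >= n_want) break
        if (round_i <= length(pools[[ind]])) neg <- c(neg, pools[[ind]][round_i])
      }
      round_i <- round_i + 1L
    }
  })
  list(positive_ids = pos, negative_ids = neg)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(code))
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat("Cohort manifest: ", nrow(x), " samples, ",
      length(unique(x$individual_id)), " individuals, ",
      length(unique(x$body_site)), " body sites, ",
      length(unique(x$timepoint)), " timepoints\n", sep = "")
  print(as.data.frame(utils::head(x, 6)))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
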