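#' Count canonical k-mers of a sample
#'
#' Every length-`k` window free of `N` contributes one occurrence to its
#' canonical form (the lexicographically smaller of the window and its reverse
#' complement), so both strands are counted together. Keys observed fewer than
#' `min_count` times are dropped; with the default `min_count = 3` only k-mers
#' that appear more than twice are kept, which suppresses singleton sequencing
#' errors.
#'
#' @param reads character vector of read sequences, or a FASTQ path.
#' @param k odd k-mer length between 3 and 31 (default 31).
#' @param min_count minimum retained occurrence count (default 3).
#' @param sample_id identifier stored with the table.
#' @return a `kmer_counts` object: list with `sample_id`, `k`, `kmer` (sorted
#'   canonical k-mers), `count`, `total_retained` (sum of retained counts).
#' @export
count_canonical_kmers <- function(reads, k = 31L, min_count = 3L,
                                  sample_id = "sample") {
  if (length(reads) == 1 && !grepl("^[ACGTNacgtn]+$", reads) && file.exists(reads))
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  res <- cpp_count_kmers(reads, as.integer(k), as.integer(min_count))
  if (length(res$kmer) == 0)
    warning("no k-mers retained for sample ", sample_id,
            " (reads shorter than k, or counts below min_count)")
  structure(list(sample_id = sample_id, k = as.integer(k),
                 kmer = res$kmer, count = res$count,
                 total_retained = res$total_retained),
            class = "kmer_counts")
}

#' Canonicalize k-mers
#'
#' @param kmers character vector of DNA strings over ACGT (length <= 31).
#' @return the canonical form of each: `min(kmer, reverse_complement(kmer))`;
#'   `NA` for strings containing other characters.
#' @export
canonical_kmers <- function(kmers) cpp_canonicalize(kmers)

#' Serialize a k-mer count table
#'
#' Two tab-separated columns (kmer, count) in sorted k-mer order, with a
#' `#sample=<id> k=<k>` header line; `.gz` paths are compressed. Round-trips
#' exactly through [read_kmer_counts()].
#'
#' @param counts a `kmer_counts` object.
#' @param path output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_kmer_counts <- function(counts, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample=%s\tk=%d", counts$sample_id, counts$k), con)
  writeLines(paste(counts$kmer, counts$count, sep = "\t"), con)
  invisible(path)
}

#' Read a serialized k-mer count table
#'
#' @param path path written by [write_kmer_counts()].
#' @return a `kmer_counts` object.
#' @export
read_kmer_counts <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  m <- regmatches(header, regexec("^#sample=([^\t]*)\tk=([0-9]+)$", header))[[1]]
  if (length(m) != 3) stop("not a k-mer count table: ", path)
  body <- readLines(con)
  parts <- strsplit(body, "\t", fixed = TRUE)
  kmer <- vapply(parts, `[`, "", 1L)
  count <- as.integer(vapply(parts, `[`, "", 2L))
  structure(list(sample_id = m[2], k = as.integer(m[3]),
                 kmer = kmer, count = count,
                 total_retained = sum(as.numeric(count))),
            class = "kmer_counts")
}

#' Merge per-sample k-mer tables into a frequency union matrix
#'
#' Rows are the union of all samples' retained canonical k-mers; the frequency
#' of k-mer i in sample j is its count divided by the sample's total retained
#' count, and the logical matrix marks presence (`frequency > 0`).
#'
#' @param tables list of `kmer_counts` sharing the same `k`.
#' @param labels named character vector mapping sample_id to `"positive"` or
#'   `"negative"`.
#' @return a `kmer_matrix`: list with `kmers`, `sample_ids`, `freq`,
#'   `logical`, `labels`, `k`.
#' @export
build_kmer_matrix <- function(tables, labels) {
  ks <- unique(vapply(tables, `[[`, 0L, "k"))
  if (length(ks) != 1) stop("all tables must share the same k")
  ids <- vapply(tables, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id among tables: ",
                               ids[duplicated(ids)][1])
  if (!all(ids %in% names(labels))) stop("labels missing for some samples")
  labels <- labels[ids]
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  kmers <- sort(unique(unlist(lapply(tables, `[[`, "kmer"), use.names = FALSE)))
  freq <- matrix(0, nrow = length(kmers), ncol = length(tables),
                 dimnames = list(NULL, ids))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    if (length(t$kmer) > 0)
      freq[match(t$kmer, kmers), j] <- t$count / t$total_retained
  }
  structure(list(kmers = kmers, sample_ids = ids, freq = freq,
                 logical = freq > 0, labels = labels, k = ks),
            class = "kmer_matrix")
}

#' Remove highly-sparse k-mers
#'
#' A k-mer is removed only when it is absent from more than
#' `max_absent_fraction` of the positive samples *and* more than
#' `max_absent_fraction` of the negative samples: such features are present in
#' too few samples of either group to contribute to classification. Row order
#' and surviving values are unchanged.
#'
#' @param matrix a `kmer_matrix` with both groups non-empty.
#' @param max_absent_fraction sparsity threshold (default 0.8).
#' @return the filtered `kmer_matrix`.
#' @export
filter_sparse <- function(matrix, max_absent_fraction = 0.8) {
  pos <- matrix$labels == "positive"
  if (!any(pos) || all(pos)) stop("both groups must be non-empty")
  absent_pos <- rowMeans(!matrix$logical[, pos, drop = FALSE])
  absent_neg <- rowMeans(!matrix$logical[, !pos, drop = FALSE])
  keep <- !(absent_pos > max_absent_fraction & absent_neg > max_absent_fraction)
  matrix$kmers <- matrix$kmers[keep]
  matrix$freq <- matrix$freq[keep, , drop = FALSE]
  matrix$logical <- matrix$logical[keep, , drop = FALSE]
  matrix
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("k-mer counts for sample '", x$sample_id, "': ", length(x$kmer),
      " canonical ", x$k, "-mers, ", format(x$total_retained, big.mark = ","),
      " retained occurrences\n", sep = "")
  invisible(x)
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("k-mer union matrix: ", length(x$kmers), " canonical ", x$k,
      "-mers x ", length(x$sample_ids), " samples (",
      sum(x$labels == "positive"), " positive / ",
      sum(x$labels == "negative"), " negative)\n", sep = "")
  invisible(x)
}
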