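#' Map reads onto contigs by exact k-mer containment
#'
#' A read maps to a contig when at least `min_shared_kmers` of its distinct
#' canonical k-mers occur exactly in the contig (either strand). The default
#' `min_shared_kmers = NULL` requires *every* k-mer of the read to be present,
#' the k-mer analogue of end-to-end alignment with zero mismatches: a read
#' crossing a sequence variant, or overhanging the contig end, does not map.
#' A read matching several contigs is assigned to the one sharing most k-mers
#' (ties to the lexicographically first `contig_id`); its depth contribution
#' covers the matched span.
#'
#' @param contigs contig data frame (`contig_id`, `sequence`, `length`).
#' @param reads character vector of read sequences.
#' @param k k-mer length (default 31).
#' @param min_shared_kmers minimum shared distinct k-mers, or `NULL` for "all
#'   k-mers of the read".
#' @return list with `counts` (named mapped-read counts per contig),
#'   `coverage` (named list of per-base raw depth vectors), `assignment`
#'   (per-read contig_id or `NA`), `n_reads`.
#' @export
map_reads <- function(contigs, reads, k = 31L, min_shared_kmers = NULL) {
  if (nrow(contigs) == 0) stop("no contigs supplied")
  ord <- order(contigs$contig_id)
  contigs <- contigs[ord, , drop = FALSE]
  res <- cpp_map_reads(reads, contigs$sequence, as.integer(k),
                       if (is.null(min_shared_kmers)) -1L
                       else as.integer(min_shared_kmers))
  counts <- stats::setNames(res$counts, contigs$contig_id)
  coverage <- stats::setNames(res$coverage, contigs$contig_id)
  assignment <- contigs$contig_id[res$assignment]
  list(counts = counts, coverage = coverage, assignment = assignment,
       n_reads = length(reads))
}

#' Reads per kilobase per million (RPKM)
#'
#' `rpkm = mapped_reads / (contig_length_kb * library_size_millions)`. The
#' library size is the sample's total read count, not the reads mapped to the
#' contig panel.
#'
#' @param mapped_reads mapped-read count(s).
#' @param contig_length contig length(s) in bp (> 0).
#' @param library_size total reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(mapped_reads, contig_length, library_size) {
  if (any(contig_length <= 0)) stop("contig length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  mapped_reads / ((contig_length / 1000) * (library_size / 1e6))
}

#' Quantify samples against a contig panel
#'
#' Maps each sample's reads onto the panel and tabulates mapped-read counts,
#' RPKM and (optionally) per-base coverage normalized per million reads.
#'
#' @param contigs contig data frame.
#' @param sample_reads named list: sample_id to character vector of reads.
#' @param k k-mer length.
#' @param min_shared_kmers see [map_reads()].
#' @param keep_coverage also return normalized per-base coverage profiles.
#' @return an `abundance_table`: list with matrices `counts` and `rpkm`
#'   (contigs x samples), `library_sizes`, `contig_lengths`, and `coverage`
#'   (list coverage\[\[contig\]\]\[\[sample\]\] when requested).
#' @export
quantify_samples <- function(contigs, sample_reads, k = 31L,
                             min_shared_kmers = NULL, keep_coverage = FALSE) {
  ids <- names(sample_reads)
  counts <- matrix(0L, nrow(contigs), length(ids),
                   dimnames = list(contigs$contig_id, ids))
  lib <- stats::setNames(lengths(sample_reads), ids)
  coverage <- if (keep_coverage)
    stats::setNames(lapply(contigs$contig_id, function(.) list()),
                    contigs$contig_id) else NULL
  for (s in ids) {
    m <- map_reads(contigs, sample_reads[[s]], k = k,
                   min_shared_kmers = min_shared_kmers)
    counts[names(m$counts), s] <- m$counts
    if (keep_coverage) {
      for (cid in contigs$contig_id)
        coverage[[cid]][[s]] <- m$coverage[[cid]] / (lib[[s]] / 1e6)
    }
  }
  lens <- stats::setNames(contigs$length, contigs$contig_id)
  rpkm <- sweep(sweep(counts, 1, lens / 1000, "/"), 2, lib / 1e6, "/")
  structure(list(counts = counts, rpkm = rpkm, library_sizes = lib,
                 contig_lengths = lens, coverage = coverage),
            class = "abundance_table")
}

#' Export a coverage heat-map matrix
#'
#' Rows are samples, columns contig positions; values are `log10(coverage+1)`
#' when `log_transform` is set (so zero coverage maps to 0).
#'
#' @param profiles named list sample_id to per-base coverage vector for one
#'   contig (e.g. `quantify_samples(...)$coverage[[contig_id]]`).
#' @param log_transform apply `log10(x + 1)` (default TRUE).
#' @param path optional TSV output path.
#' @return the matrix, invisibly when written to `path`.
#' @export
coverage_heatmap_matrix <- function(profiles, log_transform = TRUE,
                                    path = NULL) {
  lens <- unique(lengths(profiles))
  if (length(lens) != 1) stop("profiles must share one contig")
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  if (log_transform) m <- log10(m + 1)
  if (!is.null(path)) {
    utils::write.table(format(m, digits = 12, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, col.names = FALSE)
    return(invisible(m))
  }
  m
}

#' Read back a coverage heat-map matrix
#'
#' @param path TSV written by [coverage_heatmap_matrix()].
#' @return numeric matrix with sample rownames.
#' @export
read_coverage_matrix <- function(path) {
  df <- utils::read.delim(path, header = FALSE, row.names = 1)
  as.matrix(df)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table: ", nrow(x$rpkm), " contigs x ", ncol(x$rpkm),
      " samples; RPKM range [", format(min(x$rpkm), digits = 4), ", ",
      format(max(x$rpkm), digits = 4), "]\n", sep = "")
  invisible(x)
}
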