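#' Recruit reads perfectly matched by individual-specific k-mers
#'
#' A read is recruited when it contains at least `min_hits` *distinct*
#' specific canonical k-mers as exact (mismatch-free) substrings on either
#' strand. Only presence-direction k-mers are meaningful here: absence-type
#' markers cannot recruit reads from the donor.
#'
#' @param specific_kmers character vector of specific k-mers (canonical or
#'   not; canonicalized internally), or a record data frame from
#'   [detect_specific_kmers()], in which case absence-direction rows are
#'   dropped.
#' @param reads character vector of the individual's read sequences.
#' @param k k-mer length (default 31).
#' @param min_hits minimum distinct matching k-mers (default 3: "more than
#'   two").
#' @param individual_id identifier stored with the result.
#' @return a `recruited_reads` object: list with `individual_id`, `reads`,
#'   `hits` (distinct-k-mer count per recruited read), `n_input`.
#' @export
recruit_reads <- function(specific_kmers, reads, k = 31L, min_hits = 3L,
                          individual_id = "individual") {
  if (is.data.frame(specific_kmers)) {
    specific_kmers <- specific_kmers$kmer[specific_kmers$direction == "presence"]
  }
  if (length(specific_kmers) == 0) stop("no presence-direction specific k-mers")
  hits <- cpp_read_hits(reads, canonical_kmers(specific_kmers), as.integer(k))
  keep <- hits >= min_hits
  if (!any(keep)) warning("no reads recruited for ", individual_id)
  structure(list(individual_id = individual_id, reads = reads[keep],
                 hits = hits[keep], n_input = length(reads)),
            class = "recruited_reads")
}

#' Assemble recruited reads into unitig contigs
#'
#' Builds a canonical de Bruijn graph over the recruited reads' `k_asm`-mers,
#' drops nodes below the coverage floor (removing singleton sequencing-error
#' branches), compresses every maximal non-branching path into a unitig, and
#' returns unitigs of at least `min_contig_len` bp. Output order is longest
#' first, then lexicographic; each unitig is reported in its canonical
#' orientation, so the result is invariant to read order and to
#' reverse-complementing any subset of reads.
#'
#' @param reads a `recruited_reads` object or character vector of sequences.
#' @param k_asm odd assembly k-mer length (default 31).
#' @param coverage_floor minimum k-mer coverage (default 2).
#' @param min_contig_len minimum emitted contig length in bp (default 100).
#' @param individual_id recorded as the contig source (taken from the
#'   `recruited_reads` object when available).
#' @return data frame of contigs: `contig_id`, `sequence`, `length`,
#'   `individual_id`.
#' @export
assemble_unitigs <- function(reads, k_asm = 31L, coverage_floor = 2L,
                             min_contig_len = 100L,
                             individual_id = "individual") {
  if (inherits(reads, "recruited_reads")) {
    individual_id <- reads$individual_id
    reads <- reads$reads
  }
  res <- cpp_assemble_unitigs(reads, as.integer(k_asm),
                              as.integer(coverage_floor))
  seqs <- res$unitig
  if (res$n_kmers_kept == 0) {
    warning("no k-mers above the coverage floor for ", individual_id)
    seqs <- character()
  }
  seqs <- seqs[nchar(seqs) >= min_contig_len]
  seqs <- seqs[order(-nchar(seqs), seqs)]
  data.frame(contig_id = sprintf("%s_ctg%04d", individual_id,
                                 seq_along(seqs)),
             sequence = seqs, length = nchar(seqs),
             individual_id = rep(individual_id, length(seqs)),
             stringsAsFactors = FALSE)
}

#' Write contigs to FASTA
#'
#' Headers follow `individual|contig_id|length`.
#'
#' @param contigs contig data frame from [assemble_unitigs()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- sprintf("%s|%s|%d", contigs$individual_id, contigs$contig_id,
                      contigs$length)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read contigs from FASTA
#'
#' @param path FASTA written by [write_contigs_fasta()] (or any FASTA; headers
#'   without the `individual|contig_id|length` layout fall back to the full
#'   header as contig_id).
#' @return contig data frame.
#' @export
read_contigs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  ind <- vapply(parts, function(p) if (length(p) >= 2) p[1] else NA_character_, "")
  id <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], "")
  seqs <- unname(as.character(x))
  data.frame(contig_id = id, sequence = seqs, length = nchar(seqs),
             individual_id = ind, stringsAsFactors = FALSE)
}

#' @export
print.recruited_reads <- function(x, ...) {
  cat("Recruited reads for ", x$individual_id, ": ", length(x$reads), " of ",
      x$n_input, " reads (median distinct specific k-mer hits: ",
      if (length(x$hits)) stats::median(x$hits) else NA, ")\n", sep = "")
  invisible(x)
}
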