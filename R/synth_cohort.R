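#' Specification of a synthetic skin-metagenome cohort
#'
#' The simulated community has one dominant resident species whose genome
#' carries a handful of private variants per individual (the biological signal
#' the pipeline hunts for: stable strain-level variation, shared across body
#' sites and timepoints) plus background species identical across everyone.
#' Genomes are i.i.d. random sequences, so k-mer uniqueness is analyzable and
#' no repeat structure exists; they are circular, as bacterial chromosomes
#' are, so sequencing coverage is uniform with no terminal falloff.
#'
#' @param n_individuals number of cohort individuals (default 6).
#' @param n_body_sites body sites sampled per individual (default 4).
#' @param n_timepoints timepoints per site (default 2).
#' @param resident_length resident-species genome length in bp (default
#'   50000).
#' @param background_lengths lengths of the shared background genomes
#'   (default two of 30000 bp).
#' @param genome_abundances relative read fractions of (resident,
#'   backgrounds); default proportional to genome length, i.e. uniform depth.
#' @param n_private_snvs private SNVs per individual (default 5).
#' @param n_private_indels private 1-bp insertions per individual (default 1).
#' @param read_length read length in bp (default 101).
#' @param mean_depth mean per-base sequencing depth per sample (default 20).
#' @param depth_sigma log-normal spread of per-sample depth (sdlog; default 0
#'   = every sample at `mean_depth`).
#' @param error_rate per-base substitution error rate in \[0, 1) (default 0).
#' @param paired simulate 2 x `read_length` read pairs from fragments of
#'   `insert_size` (default FALSE: single-end).
#' @param insert_size paired-end fragment length (default 300).
#' @param k k-mer length used for ground-truth k-mer sets (default 31).
#' @param unstable_individual,unstable_timepoint optionally name one
#'   individual whose samples at one timepoint are simulated *without* their
#'   private variants (for stability analyses).
#' @param seed master seed; everything derives from it deterministically.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_individuals = 6L, n_body_sites = 4L,
                        n_timepoints = 2L, resident_length = 50000L,
                        background_lengths = c(30000L, 30000L),
                        genome_abundances = NULL,
                        n_private_snvs = 5L, n_private_indels = 1L,
                        read_length = 101L, mean_depth = 20,
                        depth_sigma = 0, error_rate = 0,
                        paired = FALSE, insert_size = 300L, k = 31L,
                        unstable_individual = NULL,
                        unstable_timepoint = NULL, seed = 1L) {
  lens <- c(resident_length, background_lengths)
  if (any(lens <= 0)) stop("genome lengths must be positive")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (is.null(genome_abundances)) genome_abundances <- lens / sum(lens)
  if (abs(sum(genome_abundances) - 1) > 1e-8)
    stop("genome_abundances must sum to 1")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_body_sites = as.integer(n_body_sites),
                 n_timepoints = as.integer(n_timepoints),
                 resident_length = as.integer(resident_length),
                 background_lengths = as.integer(background_lengths),
                 genome_abundances = genome_abundances,
                 n_private_snvs = as.integer(n_private_snvs),
                 n_private_indels = as.integer(n_private_indels),
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth, depth_sigma = depth_sigma,
                 error_rate = error_rate, paired = isTRUE(paired),
                 insert_size = as.integer(insert_size), k = as.integer(k),
                 unstable_individual = unstable_individual,
                 unstable_timepoint = unstable_timepoint,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Resident + background genomes, deterministic in spec$seed.
build_genomes <- function(spec) {
  with_seed(spec$seed, {
    resident <- random_genome(spec$resident_length)
    backgrounds <- lapply(spec$background_lengths, random_genome)
  })
  list(resident = resident, backgrounds = backgrounds)
}

# Sorted positions with pairwise gaps >= gap inside [lo, hi].
spaced_positions <- function(n, lo, hi, gap) {
  span <- hi - lo - (n - 1) * gap
  if (span < n)
    stop("variant placement impossible under the non-overlap constraint; ",
         "use a longer resident genome")
  y <- sort(sample(seq_len(span), n)) + lo - 1L
  y + (seq_len(n) - 1L) * gap
}

# One individual's variant table applied to the resident genome.
apply_variants <- function(genome, variants) {
  if (nrow(variants) == 0) return(genome)
  v <- variants[order(-variants$pos), , drop = FALSE]  # back-to-front
  for (i in seq_len(nrow(v))) {
    genome <- paste0(substr(genome, 1, v$pos[i] - 1), v$alt[i],
                     substr(genome, v$pos[i] + nchar(v$ref[i]),
                            nchar(genome)))
  }
  genome
}

plant_cohort_variants <- function(spec, genomes) {
  n_var <- spec$n_private_snvs + spec$n_private_indels
  total <- n_var * spec$n_individuals
  margin <- spec$read_length + spec$k
  gap <- 4L * spec$read_length  # keeps each variant's contig isolated
  with_seed(spec$seed + 1L, {
    pos <- spaced_positions(total, margin,
                            spec$resident_length - margin, gap)
    owner <- sample(rep(seq_len(spec$n_individuals), n_var))
    variants <- lapply(seq_len(spec$n_individuals), function(i) {
      p <- sort(pos[owner == i])
      is_indel <- seq_along(p) > spec$n_private_snvs
      # SNVs first (positions shuffled by ownership already), then insertions
      ref <- substring(genomes$resident, p, p)
      alt <- character(length(p))
      for (j in seq_along(p)) {
        if (!is_indel[j]) {
          alt[j] <- sample(setdiff(c("A", "C", "G", "T"), ref[j]), 1)
        } else {
          alt[j] <- paste0(ref[j], sample(c("A", "C", "G", "T"), 1))
        }
      }
      data.frame(individual_id = individual_label(i), pos = p, ref = ref,
                 alt = alt, type = ifelse(is_indel, "ins", "snv"),
                 stringsAsFactors = FALSE)
    })
  })
  names(variants) <- vapply(seq_len(spec$n_individuals), individual_label, "")
  variants
}

individual_label <- function(i) sprintf("I%02d", i)

# k-mer set of a circular genome: windows wrap across the origin.
genome_kmer_set <- function(genome, k) {
  circ <- paste0(genome, substr(genome, 1L, k - 1L))
  cpp_count_kmers(circ, as.integer(k), 1L)$kmer
}

#' Simulate a synthetic cohort with planted private variants
#'
#' Builds the genomes, derives per-individual resident haplotypes, simulates
#' FASTQ reads for every (individual, body site, timepoint) sample, writes a
#' manifest, and returns the full ground truth: each individual's variants and
#' the set of canonical k-mers unique to their haplotype (absent from the
#' reference resident genome, the backgrounds, and every other haplotype).
#' Everything is deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @param gzip write gzipped FASTQ (default FALSE: plain text, byte-stable).
#' @return list with `manifest` (a `cohort_manifest`; also written to
#'   `manifest.tsv`), `truth` (per individual: `variants` data frame and
#'   `kmers`), `genomes`, `spec`, `dir`.
#' @export
simulate_cohort <- function(spec, dir = tempfile("cohort"), gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- build_genomes(spec)
  variants <- plant_cohort_variants(spec, genomes)
  inds <- names(variants)
  haplotypes <- lapply(inds, function(i)
    apply_variants(genomes$resident, variants[[i]]))
  names(haplotypes) <- inds

  # ground-truth k-mers: haplotype k-mers absent from every other genome
  all_sets <- c(list(reference = genome_kmer_set(genomes$resident, spec$k)),
                lapply(genomes$backgrounds, genome_kmer_set, k = spec$k),
                lapply(haplotypes, genome_kmer_set, k = spec$k))
  names(all_sets) <- c("reference",
                       paste0("bg", seq_along(genomes$backgrounds)), inds)
  truth <- lapply(inds, function(i) {
    others <- unlist(all_sets[setdiff(names(all_sets), i)], use.names = FALSE)
    list(variants = variants[[i]],
         kmers = sort(setdiff(all_sets[[i]], others)))
  })
  names(truth) <- inds

  rows <- list()
  with_seed(spec$seed + 2L, {
    for (i in inds) {
      for (s in seq_len(spec$n_body_sites)) {
        for (t in seq_len(spec$n_timepoints)) {
          sample_id <- sprintf("%s_S%d_T%d", i, s, t)
          tp <- sprintf("T%d", t)
          hap <- haplotypes[[i]]
          if (!is.null(spec$unstable_individual) &&
              i == spec$unstable_individual &&
              tp == spec$unstable_timepoint) {
            hap <- genomes$resident  # this slice lost its private variants
          }
          src <- c(list(hap), genomes$backgrounds)
          files <- write_sample_fastq(src, spec, sample_id, dir, gzip)
          rows[[sample_id]] <- data.frame(
            sample_id = sample_id, individual_id = i,
            body_site = sprintf("S%d", s), timepoint = tp,
            fastq_1 = files[1],
            fastq_2 = if (length(files) > 1) files[2] else NA_character_,
            n_reads = attr(files, "n_reads"), stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  class(manifest) <- c("cohort_manifest", "data.frame")
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  write_truth(truth, dir)
  genome_set <- Biostrings::DNAStringSet(c(reference = genomes$resident,
                                           stats::setNames(
                                             unlist(genomes$backgrounds),
                                             paste0("bg", seq_along(genomes$backgrounds)))))
  Biostrings::writeXStringSet(genome_set, file.path(dir, "genomes.fasta"))
  list(manifest = manifest, truth = truth, genomes = genomes,
       haplotypes = haplotypes, spec = spec, dir = dir)
}

write_truth <- function(truth, dir) {
  vt <- do.call(rbind, lapply(truth, `[[`, "variants"))
  utils::write.table(vt, file.path(dir, "truth_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  km <- do.call(rbind, lapply(names(truth), function(i)
    data.frame(individual_id = i, kmer = truth[[i]]$kmers,
               stringsAsFactors = FALSE)))
  utils::write.table(km, file.path(dir, "truth_kmers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Simulate one sample from its source genomes and write FASTQ; assumes the
# caller set up the RNG stream. Returns file path(s) with n_reads attribute.
write_sample_fastq <- function(src_genomes, spec, sample_id, dir, gzip) {
  lens <- vapply(src_genomes, nchar, 0L)
  depth <- spec$mean_depth
  if (spec$depth_sigma > 0)
    depth <- depth * exp(stats::rnorm(1, 0, spec$depth_sigma) -
                           spec$depth_sigma^2 / 2)
  frag_len <- if (spec$paired) spec$insert_size else spec$read_length
  bases_per_unit <- if (spec$paired) 2L * spec$read_length else spec$read_length
  n_units <- max(1L, round(depth * sum(lens) / bases_per_unit))
  per_genome <- as.vector(stats::rmultinom(1, n_units, spec$genome_abundances))
  frags <- character(0)
  for (g in seq_along(src_genomes)) {
    n <- per_genome[g]
    if (n == 0) next
    # genomes are circular (as bacterial chromosomes are): fragments may wrap
    # the origin, giving uniform coverage with no terminal falloff
    ext <- paste0(src_genomes[[g]], substr(src_genomes[[g]], 1L, frag_len - 1L))
    start <- sample.int(lens[g], n, replace = TRUE)
    frags <- c(frags, substring(ext, start, start + frag_len - 1L))
  }
  flip <- stats::runif(length(frags)) < 0.5
  if (any(flip))
    frags[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(frags[flip])))
  if (spec$paired) {
    r1 <- substring(frags, 1L, spec$read_length)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substring(frags, frag_len - spec$read_length + 1L, frag_len))))
    reads <- list(r1, r2)
  } else {
    reads <- list(frags)
  }
  if (spec$error_rate > 0) {
    reads <- lapply(reads, function(rs) {
      n_err <- stats::rbinom(length(rs), spec$read_length, spec$error_rate)
      tot <- sum(n_err)
      if (tot == 0) return(rs)
      idx <- rep(seq_along(rs), n_err)
      pos <- ceiling(stats::runif(tot) * spec$read_length)
      off <- sample.int(3L, tot, replace = TRUE)
      cpp_apply_subs(rs, idx, pos, off)
    })
  }
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  qual <- strrep("I", spec$read_length)
  files <- character(length(reads))
  for (m in seq_along(reads)) {
    suffix <- if (spec$paired) sprintf("_R%d", m) else ""
    path <- file.path(dir, paste0(sample_id, suffix, ext))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    ids <- sprintf("@%s:%d%s", sample_id, seq_along(reads[[m]]),
                   if (spec$paired) sprintf("/%d", m) else "")
    writeLines(rbind(ids, reads[[m]], "+", qual), con)
    close(con)
    files[m] <- path
  }
  attr(files, "n_reads") <- length(reads[[1]]) * length(reads)
  files
}

#' Simulate an out-of-cohort sample
#'
#' Builds a fresh resident haplotype with its own private variants, placed
#' away from every cohort individual's variant loci (so at zero error rate it
#' shares none of their ground-truth k-mers), over the same background
#' genomes, and simulates one sample from it.
#'
#' @param spec the [cohort_spec()] the cohort was simulated from.
#' @param seed seed for the outgroup's variants and reads (independent of the
#'   cohort's).
#' @param dir output directory.
#' @return list with `fastq`, `sample_id`, `variants`, `n_reads`.
#' @export
make_outgroup_sample <- function(spec, seed = spec$seed + 1000L,
                                 dir = tempfile("outgroup")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- build_genomes(spec)
  cohort_pos <- sort(unlist(lapply(plant_cohort_variants(spec, genomes),
                                   `[[`, "pos"), use.names = FALSE))
  n_var <- spec$n_private_snvs + spec$n_private_indels
  margin <- spec$read_length + spec$k
  gap <- 4L * spec$read_length
  sample_id <- sprintf("OUT%04d", seed %% 10000L)
  files <- NULL
  with_seed(seed, {
    # rejection-sample variant positions clear of every cohort locus
    pos <- integer(0)
    tries <- 0L
    while (length(pos) < n_var) {
      cand <- sample.int(spec$resident_length - 2L * margin, 1L) + margin
      if (all(abs(cand - cohort_pos) >= gap) &&
          (length(pos) == 0 || all(abs(cand - pos) >= gap))) {
        pos <- c(pos, cand)
      }
      tries <- tries + 1L
      if (tries > 10000L)
        stop("could not place outgroup variants; use a longer resident genome")
    }
    pos <- sort(pos)
    ref <- substring(genomes$resident, pos, pos)
    is_indel <- seq_along(pos) > spec$n_private_snvs
    alt <- vapply(seq_along(pos), function(j) {
      if (is_indel[j]) paste0(ref[j], sample(c("A", "C", "G", "T"), 1))
      else sample(setdiff(c("A", "C", "G", "T"), ref[j]), 1)
    }, "")
    variants <- data.frame(individual_id = sample_id, pos = pos, ref = ref,
                           alt = alt,
                           type = ifelse(is_indel, "ins", "snv"),
                           stringsAsFactors = FALSE)
    hap <- apply_variants(genomes$resident, variants)
    files <- write_sample_fastq(c(list(hap), genomes$backgrounds), spec,
                                sample_id, dir, gzip = FALSE)
  })
  list(fastq = as.character(files), sample_id = sample_id,
       variants = variants, n_reads = attr(files, "n_reads"))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec: ", x$n_individuals, " individuals x ",
      x$n_body_sites, " sites x ", x$n_timepoints, " timepoints; resident ",
      x$resident_length, " bp (+", length(x$background_lengths),
      " backgrounds), ", x$n_private_snvs, " SNVs + ", x$n_private_indels,
      " indels each; depth ", x$mean_depth, "x, error ", x$error_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
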