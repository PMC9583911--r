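test_that("cohort simulation is fully deterministic in its seed", {
  spec <- tiny_spec()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(spec, dir = d1)
  s2 <- simulate_cohort(spec, dir = d2)
  expect_equal(as.data.frame(s1$manifest)[, -c(5, 6)],
               as.data.frame(s2$manifest)[, -c(5, 6)])
  expect_equal(s1$truth, s2$truth)
  for (s in s1$manifest$sample_id[c(1, 5, 12)]) {
    f1 <- s1$manifest$fastq_1[s1$manifest$sample_id == s]
    f2 <- s2$manifest$fastq_1[s2$manifest$sample_id == s]
    expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTQ
  }
})

test_that("a single SNV leaves exactly k private canonical k-mers", {
  spec <- cohort_spec(n_individuals = 1L, n_body_sites = 1L, n_timepoints = 1L,
                      resident_length = 4000L, background_lengths = 2000L,
                      n_private_snvs = 1L, n_private_indels = 0L,
                      mean_depth = 5, seed = 11)
  sim <- simulate_cohort(spec, dir = withr::local_tempdir())
  expect_length(sim$truth$I01$kmers, 31)
  # brute-force oracle: sliding windows canonicalized via Biostrings
  v <- sim$truth$I01$variants
  hap <- sim$haplotypes$I01
  win <- substring(hap, (v$pos - 30):v$pos, (v$pos):(v$pos + 30))
  canon <- pmin(win, rc_str(win))
  expect_setequal(sim$truth$I01$kmers, canon)
})

test_that("truth k-mer sets are disjoint and recoverable by set difference", {
  sim <- tiny_sim()
  ks <- lapply(sim$truth, `[[`, "kmers")
  for (i in seq_along(ks))
    for (j in seq_along(ks))
      if (i != j) expect_length(intersect(ks[[i]], ks[[j]]), 0)
  # independent reconstruction from the haplotypes themselves
  all_seqs <- c(sim$genomes$resident, unlist(sim$genomes$backgrounds),
                unlist(sim$haplotypes))
  off <- 1 + length(sim$genomes$backgrounds)
  for (ind in names(sim$truth)) {
    mine <- count_canonical_kmers(sim$haplotypes[[ind]], 31, 1)$kmer
    others <- count_canonical_kmers(
      all_seqs[-(off + match(ind, names(sim$haplotypes)))], 31, 1)$kmer
    expect_setequal(sim$truth[[ind]]$kmers, setdiff(mine, others))
  }
})

test_that("error-free reads are exact genome substrings at the right depth", {
  sim <- tiny_sim()
  spec <- sim$spec
  reads <- read_sample_seqs(sim$manifest, sim$manifest$sample_id[1])
  total_len <- spec$resident_length + sum(spec$background_lengths)
  depth <- length(reads) * spec$read_length / total_len
  expect_lt(abs(depth - spec$mean_depth) / spec$mean_depth, 0.1)
  hay <- c(sim$haplotypes$I01, unlist(sim$genomes$backgrounds))
  hay <- paste0(hay, substr(hay, 1, 100))  # genomes are circular
  hay <- paste(c(hay, rc_str(hay)), collapse = "|")
  for (r in reads[seq(1, length(reads), by = 40)])
    expect_true(grepl(r, hay, fixed = TRUE))
})

test_that("depth heterogeneity and paired mode behave as configured", {
  spec <- tiny_spec(depth_sigma = 0.6)
  sim <- simulate_cohort(spec, dir = withr::local_tempdir())
  expect_gt(stats::sd(sim$manifest$n_reads), 0)

  pspec <- cohort_spec(n_individuals = 1L, n_body_sites = 1L,
                       n_timepoints = 1L, resident_length = 3000L,
                       background_lengths = 1500L, n_private_snvs = 1L,
                       n_private_indels = 0L, mean_depth = 4, paired = TRUE,
                       seed = 3)
  psim <- simulate_cohort(pspec, dir = withr::local_tempdir())
  expect_false(is.na(psim$manifest$fastq_2[1]))
  m <- validate_read_counts(psim$manifest)
  expect_equal(m$n_reads[1], psim$manifest$n_reads[1])
})

test_that("outgroup samples carry no cohort truth k-mers and vary by seed", {
  sim <- tiny_sim()
  og <- make_outgroup_sample(sim$spec, seed = 900,
                             dir = withr::local_tempdir())
  reads <- as.character(Biostrings::readDNAStringSet(og$fastq,
                                                     format = "fastq"))
  all_truth <- unlist(lapply(sim$truth, `[[`, "kmers"), use.names = FALSE)
  hits <- suppressWarnings(recruit_reads(all_truth, reads, min_hits = 1,
                                         individual_id = "out"))
  expect_length(hits$reads, 0)
  og2 <- make_outgroup_sample(sim$spec, seed = 901,
                              dir = withr::local_tempdir())
  expect_false(identical(og$variants$pos, og2$variants$pos))
})

test_that("an unstable individual loses its k-mers at the affected timepoint", {
  spec <- tiny_spec(unstable_individual = "I01", unstable_timepoint = "T2")
  sim <- simulate_cohort(spec, dir = withr::local_tempdir())
  t2 <- sim$manifest[sim$manifest$individual_id == "I01" &
                       sim$manifest$timepoint == "T2", ]
  reads <- read_sample_seqs(sim$manifest, t2$sample_id[1])
  got <- suppressWarnings(recruit_reads(sim$truth$I01$kmers, reads,
                                        min_hits = 1, individual_id = "I01"))
  expect_length(got$reads, 0)
  # ...while T1 samples still carry them
  t1 <- sim$manifest[sim$manifest$individual_id == "I01" &
                       sim$manifest$timepoint == "T1", ]
  reads1 <- read_sample_seqs(sim$manifest, t1$sample_id[1])
  got1 <- recruit_reads(sim$truth$I01$kmers, reads1, min_hits = 1,
                        individual_id = "I01")
  expect_gt(length(got1$reads), 0)
})

test_that("impossible variant placement fails with guidance", {
  expect_error(simulate_cohort(cohort_spec(resident_length = 2000L,
                                           background_lengths = 1000L),
                               dir = withr::local_tempdir()),
               "longer")
})
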