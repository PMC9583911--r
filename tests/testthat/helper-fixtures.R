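# Shared fixtures and independent oracles. Everything is generated in code;
# the small simulated cohort is cached so several test files can reuse it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random sequence with no repeated canonical k-mer (so its de Bruijn graph is
# a simple path).
repeat_free_seq <- function(len, k) {
  repeat {
    g <- random_seq(len)
    if (all(count_canonical_kmers(g, k = k, min_count = 1)$count == 1)) return(g)
  }
}

# Minimal kmer_counts object for matrix-level tests.
fake_table <- function(id, kmers, count = 3L, k = 31L) {
  kmers <- sort(unique(kmers))
  structure(list(sample_id = id, k = as.integer(k), kmer = kmers,
                 count = rep(as.integer(count), length(kmers)),
                 total_retained = as.numeric(count) * length(kmers)),
            class = "kmer_counts")
}

random_kmer <- function(n, k = 31L) {
  vapply(seq_len(n), function(i) random_seq(k), "")
}

tiny_spec <- function(...) {
  cohort_spec(n_individuals = 3L, n_body_sites = 2L, n_timepoints = 2L,
              resident_length = 12000L, background_lengths = 6000L,
              n_private_snvs = 2L, n_private_indels = 1L,
              mean_depth = 15, seed = 5L, ...)
}

tiny_sim <- function() cached("tiny_sim", simulate_cohort(tiny_spec()))

tiny_config <- function(...) {
  pipeline_config(cv_folds = 3L, roc_step = 0.01, seed = 5L, ...)
}

tiny_fit <- function() cached("tiny_fit", suppressMessages(
  fingerprint_fit(tiny_sim()$manifest, tiny_config(), quiet = TRUE)))

# A file-less manifest for cohort bookkeeping tests.
synthetic_manifest <- function(n_per_ind, n_reads = NULL) {
  ids <- unlist(lapply(names(n_per_ind), function(i)
    sprintf("%s_x%02d", i, seq_len(n_per_ind[[i]]))))
  df <- data.frame(
    sample_id = ids,
    individual_id = sub("_x[0-9]+$", "", ids),
    body_site = rep_len(c("Fh", "Vf", "Ph"), length(ids)),
    timepoint = rep_len(c("T1", "T2"), length(ids)),
    fastq_1 = paste0("/nonexistent/", ids, ".fastq"),
    stringsAsFactors = FALSE)
  df$n_reads <- if (is.null(n_reads)) 1000L else n_reads
  as_cohort_manifest(df)
}

# ---- independent oracles -----------------------------------------------------

# Brute-force single-k-mer predictor scoring via explicit confusion matrices.
oracle_score_kmer <- function(row, labels) {
  pos <- labels == "positive"
  best <- NULL
  for (dir in c("presence", "absence")) {
    pred_pos <- if (dir == "presence") as.logical(row) else !as.logical(row)
    tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
    tn <- sum(!pred_pos & !pos); fp <- sum(pred_pos & !pos)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    ass <- (sens + spec) / 2
    if (is.null(best) || ass > best$ass)  # strict: ties keep presence
      best <- list(direction = dir, sensitivity = sens, specificity = spec,
                   ass = ass)
  }
  best
}

# All-pairs AUC.
oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

oracle_gini <- function(labels) {
  p <- table(labels) / length(labels)
  s <- 0
  for (a in names(p)) for (b in names(p)) if (a != b) s <- s + p[[a]] * p[[b]]
  s
}

oracle_gini_index <- function(labels, values, threshold) {
  above <- values >= threshold
  out <- 0
  for (part in list(labels[above], labels[!above]))
    if (length(part) > 0) out <- out + length(part) / length(labels) *
      oracle_gini(part)
  out
}

# Naive exhaustive ROC grid scan (first minimum wins).
oracle_threshold <- function(pos, neg, step) {
  grid <- seq(0, max(pos, neg), by = step)
  best_t <- grid[1]; best_d <- Inf
  for (t in grid) {
    sens <- mean(pos >= t)
    fpr <- mean(neg >= t)
    d <- (1 - sens)^2 + fpr^2
    if (d < best_d - 1e-15) { best_d <- d; best_t <- t }
  }
  best_t
}
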