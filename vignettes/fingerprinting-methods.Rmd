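---
title: "Microbial DNA fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial DNA fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Human skin hosts resident microbial species whose strain-level genetic
variants are largely private to their host, stable over months to years, and
shared across body sites. Those variants make the skin microbiome a candidate
forensic marker: given shotgun metagenomic reads from an unknown skin swab and
a panel of candidate donors, we want to name the donor -- or say "none of
them". `kmerprint` implements a reference-free procedure for this: it never
aligns to a species reference, so it needs no prior knowledge of which
organism carries the signal.

The procedure has four stages, run end to end by `fingerprint_fit()`.

## Stage 1: cohort preparation

Samples with extreme low depth cannot support presence/absence calls, so any
sample whose read count falls strictly below
`max(median(reads) / 10, absolute_min_reads)` is dropped, as are samples from
body sites dominated by environment rather than host (both knobs sit in
`pipeline_config()`; the site list is empty by default because the synthetic
cohort has no such sites). The remaining samples are split 70/30 into
training and test sets, stratified by individual, rounding toward train. For
each target individual the training negatives (everyone else's samples) are
undersampled to `undersample_ratio` (default 2) negatives per positive,
drawn round-robin across the other individuals so no single individual
dominates the negative class.

## Stage 2: individual-specific k-mers

Each sample is reduced to its canonical 31-mer counts: every N-free window
counts toward the lexicographic minimum of itself and its reverse complement,
and counts below 3 ("more than twice") are dropped, which removes almost all
singleton sequencing-error k-mers. Counts are normalized by the sample's
total retained occurrences (the natural reading that makes the entries
frequencies; the alternative denominator, distinct keys, would change scale
only -- the downstream logicalization is unaffected). Samples are merged into
a union matrix, a k-mer is kept only if it is present in at least 20% of one
of the groups (the sparsity filter), and every surviving k-mer is scored as a
one-feature logical predictor in both directions:

* presence predicts the target individual, or
* absence predicts the target individual;

each direction is summarized by ASS = (sensitivity + specificity) / 2, the
direction with the larger ASS wins (exact ties go to presence, because a
usable fingerprint must be observable in its donor), and k-mers with
ASS >= theta1 are called individual-specific. theta1 defaults to 0.80 and is
raised to 0.9 for noisy data; values below 0.5 are meaningless for a
two-direction predictor, so the configuration rejects them.

Absence-direction k-mers (reference alleles at the donor's variant loci, or
genuinely missing loci) are reported -- they are informative -- but are not
carried into assembly: a contig must be sequenced from the donor's own reads.

## Stage 3: fingerprint markers

Reads containing at least `min_hits = 3` distinct specific k-mers as exact
substrings (either strand) are recruited and assembled by a built-in
single-k de Bruijn unitig assembler: canonical 31-mer nodes, a coverage floor
of 2 to clip error branches, maximal non-branching paths emitted as contigs
of >= 100 bp, longest first. A full iterative multi-k assembler would be
overkill here: recruited read sets are tiny and variant-bearing contigs are a
few hundred bp, so non-branching paths suffice; `assemble_unitigs()` can be
bypassed by supplying any external assembler's FASTA through
`read_contigs_fasta()`.

Candidate contigs are quantified in every training sample by k-mer
pseudo-mapping. The mapping rule deserves a paragraph, because it is the one
place where this implementation deliberately tightens a naive k-mer overlap
heuristic. A read maps to a contig when **all** of its canonical 31-mers
occur in the contig (`min_shared_kmers = NULL`). This is the k-mer analogue
of end-to-end alignment with zero mismatches: a read that crosses a variant
position, or hangs over the contig end, does not map. A permissive overlap
rule (say, 10 shared k-mers) would let non-donor reads map onto the
fingerprint's reference-identical flanks, and for a contig carrying a single
variant the donor and non-donor mapped-read counts then become almost equal
-- the RPKM contrast that the decision thresholds rely on disappears
entirely. The numeric knob remains available for experimentation.

Abundance is expressed as RPKM = mapped reads / (contig kb x library
millions), with the library defined as the sample's total reads (a panel
only a few contigs wide would make "per million panel-mapped reads"
degenerate). Contigs with mean RPKM <= 0.01 across the individual's training
samples are discarded; the rest are ranked by mean validation AUC
(Mann-Whitney form, ties at 0.5 weight) over stratified 6-fold
cross-validation, ties broken toward longer contigs -- a longer fingerprint
is more unique in a wider population -- then contig id. The winner's decision
threshold is the ROC-optimal threshold (grid over [0, max observed] with
step 0.001, classify positive at RPKM >= t, minimize Euclidean distance to
the (sensitivity 1, specificity 1) corner, ties to the smallest grid point)
computed on each fold's training portion and averaged over folds. Learning
the threshold on the training side of each fold treats it as a model
parameter; the source procedure is ambiguous on this point and the validation
side would be equally defensible. Note the smallest-tie rule makes
thresholds hug the largest negative observation; when every training
negative is exactly zero the threshold is one grid step above zero, which is
deliberate but means a single spuriously mapped read can cross it.

The "6-fold LOOCV" phrase that sometimes describes this procedure is
self-contradictory; stratified 6-fold cross-validation is what is
implemented, and the fold counts it produces are consistent with that
reading.

## Stage 4: the identification tree

Each individual contributes one binary rule: "fingerprint RPKM >= threshold".
The tree orders these rules greedily by the branch-weighted Gini index
`sum_v |D_v|/|D| * Gini(D_v)` with `Gini(D) = 1 - sum_k p_k^2` over the
node's training samples; the attribute minimizing the index decides next
(ties: higher above-branch recall, then individual id). The above branch is
committed as that individual's leaf even when impure -- impurity is recorded
as the leaf's precision rather than re-split, each individual appears at most
once per root-to-leaf path, and thresholds are *not* re-learned by the tree:
the tree chooses only the order of fixed rules. When the attributes are
exhausted the remaining branch is the unlabeled leaf, which is what an
out-of-cohort sample reaches when it exceeds no fingerprint's threshold.
Evaluation counts unlabeled in-cohort samples as errors.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the package is tested
under: 6 individuals x 4 body sites x 2 timepoints; one 50 kb resident
genome carrying, per individual, 5 private SNVs and 1 private 1-bp insertion
(variant loci spaced >= 4 read lengths apart so each produces an isolated
contig, and kept clear of the replication origin where coordinates wrap);
two 30 kb
background genomes shared identically by everyone (all genomes circular, as
bacterial chromosomes are, so coverage is uniform and no k-mer sits in a
low-coverage terminal region); 101 bp single-end reads
at 20x mean depth (read counts proportional to genome length, i.e. uniform
coverage); substitution errors at a configurable rate (0 by default, 0.5% in
the robustness checks). Depth is exact by default (`depth_sigma = 0`);
a log-normal per-sample spread is available to exercise the QC filter.
`make_outgroup_sample()` draws a fresh haplotype with its own variants, away
from every cohort locus, to probe the unlabeled path. Ground truth -- the
variant table and the canonical k-mers unique to each haplotype -- is
returned and written alongside the reads, and the truth k-mer sets are
pairwise disjoint by construction.

What the generator does *not* emulate matters for interpreting green tests:
genomes are i.i.d. random sequences, so there are no repeats, no
within-species pangenome structure, no GC bias, no indel sequencing errors,
no adapter contamination, and the community has three species rather than
hundreds. Passing tests demonstrate the machinery is correct under the
stated model, not that real skin metagenomes will separate this cleanly; on
real data the interesting failure modes are shared strains between
cohabiting individuals and abundance drift of the resident species.

## Numerical choices and degenerate inputs

* k = 31 (odd k means no k-mer is its own reverse complement; 31 fits in one
  64-bit word at 2 bits/base). k > 31 is rejected.
* N-containing windows are skipped, never errors; reads with characters
  outside ACGTN are rejected at load.
* The ROC grid is scanned in 5-million-point chunks with binary search per
  chunk, so step 0.001 stays usable when RPKM values reach the thousands.
* An individual with fewer positives than folds gets its fold count capped
  (with a warning); a fold without both classes is an error.
* All randomness (split, undersampling, folds, simulation) flows from
  explicit integer seeds through a scoped RNG helper, so fits are exactly
  reproducible and the global RNG state is never disturbed.
* Problem sizes in the test suite: the acceptance checks run the full
  6 x 4 x 2 cohort (about one million reads) once error-free and three times
  at 0.5% error, plus a 3 x 3 x 3 cohort for the stability analyses; unit
  tests use a 3 x 2 x 2 cohort with a 12 kb resident genome.

## Known limitations

* Exact-match semantics everywhere: a variant within 31 bp of a planted
  locus on a *different* haplotype background, or error rates much above 1%,
  will erode recruitment and mapping before detection fails.
* Contigs shorter than about 2 read lengths cannot be distinguished from
  their flanks by end-to-end mapping of full-length reads.
* The decision-threshold tie rule favors sensitivity over a safety margin;
  deployments against open populations may prefer the midpoint between the
  groups (not implemented, by fidelity to the described procedure).
* Single-threaded by design at this cohort scale; `--threads` in the CLI is
  accepted for interface stability only.
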