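---
title: "Somatic alteration detection in matched tumor/normal pairs: methods"
author: "somaticpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic alteration detection in matched tumor/normal pairs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticpair)
```

# Overview

`somaticpair` implements four detectors for somatic alterations in matched
tumor/normal whole-genome sequencing, together with a read-pair simulator
that produces data with a fully known truth set. The package targets the
analysis situation of clinical cancer WGS: a tumor biopsy of limited purity
("cellularity", the fraction of cells that are tumor) sequenced alongside a
blood-derived germline sample, both at moderate depth (roughly 30--60x).
Every somatic signal in the tumor is diluted by cellularity, while germline
variation — three orders of magnitude more abundant — must be subtracted via
the matched normal.

This vignette explains each method, its assumptions and tunable parameters,
the design decisions taken where a choice was genuinely open, and what the
simulator does and does not emulate.

# The KS-like genotype caller and somatic SNVs

## Model

At a locus, the sequenced bases on one strand form an empirical distribution
$p$ over the alphabet (A, C, G, T). For a diploid genotype $g = \{a_1,
a_2\}$ and a per-strand error probability $e$, the expected distribution is

$$ q_g(b) = \sum_{i=1}^{2} \frac{1}{2}
   \begin{cases} 1 - e & b = a_i \\ e/3 & b \ne a_i \end{cases} $$

and the caller scores each of the 10 unordered diploid genotypes by a
Kolmogorov–Smirnov-like distance between $p$ and $q_g$: the maximum
absolute difference of the cumulative sums over the fixed order
A < C < G < T. The statistic is non-parametric, symmetric, bounded in
$[0,1]$, and zero exactly when the distributions coincide
(`ks_distance()`).

Base qualities enter in two places:

* **Zero-quality trimming.** Bases with phred quality 0 are removed from
  the pileup before any comparison (`trim_zero_quality()`); they carry no
  information and would otherwise distort the empirical distribution.
* **The strand error rate.** $e$ is the mean of $10^{-Q/10}$ over the
  strand's retained bases (`locus_error_rate()`). Per-read quality
  weighting was considered and rejected: a single pooled rate keeps the
  expected distribution closed-form, testable against an independent
  oracle, and empirically indistinguishable at WGS depths.

The per-strand structure is the caller's main false-positive defense: the
combined call minimises the *worst* strand distance, and a non-reference
call is demoted to ambiguous unless each strand's own best genotype
contains the same non-reference allele. A variant seen on one strand only —
the signature of many alignment and chemistry artifacts — is therefore
never called.

## Somatic workflow

Somatic status combines two per-locus tests (`call_somatic_snvs()`):

1. **Tumor side — Variant Consensus.** To limit false negatives at diluted
   allele fractions, the tumor is *not* required to yield a confident
   diploid genotype (at VAF $\times$ cellularity of 0.2 the tumor column is
   between genotypes). Instead the most frequent non-reference allele is
   reported if it has at least `consensus_min_alt_per_strand` supporting
   reads on *each* strand and a pooled fraction at least
   `consensus_min_alt_fraction`.
2. **Normal side — high-quality hom-ref.** The matched normal must be
   callable homozygous reference with combined distance at most `hq_d_max`,
   depth at least `hq_min_depth`, and pooled non-reference fraction at most
   `hq_max_alt_fraction`. This gate is deliberately conservative: a normal
   with any hint of the alt allele (a germline het, a shallow column, or
   even a single miscall at depth below 50 under the default 2% fraction
   cap) blocks the call. The cost is a ~2% recall loss at 40x from stray
   normal miscalls; the benefit is that germline leakage into the somatic
   set is essentially impossible.

Two named threshold bundles, `strict` and `lenient`, run in parallel when
`profile = "both"`, and each call records its provenance
(strict/lenient/both) — a machine-readable replacement for compiling and
visually reviewing two call sets. Every strict threshold is at least as
tight as its lenient counterpart, so strict calls nest inside lenient ones.

Defaults (all configurable via `snv_params()`): lenient
{2 alt/strand, 5% pooled fraction, $D \le 0.2$, depth $\ge 6$},
strict {3 alt/strand, 10%, $D \le 0.1$, depth $\ge 10$}; hom-ref gates
{depth $\ge 8$, $D \le 0.05$, alt fraction $\le 2\%$}. The per-strand
depth floors (2 lenient / 3 strict) mirror the consensus alt-count floors.
These are this package's quantification of a published workflow whose
exact thresholds were never printed; they are deliberately exposed as
parameters rather than buried as constants.

# Copy-number scanning

Physical coverage — the number of DNA *fragments* whose outer span covers a
base, as opposed to read coverage — is computed per sample from proper
pairs after an insert-size gate: fragments longer than mean + 3 SD of the
sample's insert distribution are excluded (`estimate_insert_model()`,
`physical_coverage()`). Physical coverage is the natural statistic for CNV
detection from paired ends: each ~300 bp fragment is one draw from the
underlying copy-number process, and spanning the full insert roughly
triples the per-base evidence relative to read coverage.

The scanner then:

1. averages physical coverage in 2 kb windows sliding at 1 kb
   (`window_coverage()`); 2 kb matches the method's resolution target, the
   half-window step smooths boundaries while keeping window width — and
   thus the noise level — constant. Trailing partial windows are dropped
   rather than rescaled so every window is statistically comparable.
2. replaces raw window coverages of zero by `zero_replacement` (default 1),
   so homozygous deletions produce a finite, depth-dependent floor rather
   than $-\infty$. At 40x with 300 bp inserts the floor sits near
   $\log_2(1/60) \approx -5.9$; at lower depth it rises toward $-3$. The
   replacement happens *before* normalization — the alternative order
   (normalize, then floor) makes the floor depth-independent but was
   rejected because it can mask genuine shallow coverage.
3. normalizes each sample by its genome-wide median positive window
   coverage (`normalize_windows()`), cancelling tumor/normal depth
   differences and staying robust to focal events;
4. masks windows whose normalized germline coverage exceeds $2^3$
   (`repeat_mask_log2 = 3`): collapsed repeats such as centromeres attract
   reads from many true loci and would otherwise produce spurious ratios.
   Masked windows carry no ratio at all; every emitted ratio is finite.
5. reports $\log_2(\text{tumor}/\text{normal})$ per window and merges
   maximal runs of windows at or beyond $|\log_2| \ge 1$ into gain/loss
   segments (`segment_calls()`).

A caveat worth knowing: a single-copy gain on a diploid background sits at
$\log_2 = 1$ *exactly*, i.e. on the default call threshold, so window noise
fragments such an event into several adjacent segments rather than one.
The windows' mean ratio is unbiased (the acceptance checks assert it within
$\pm 0.25$ of 1 at 40x); users wanting single contiguous segments for
borderline events, or working at low cellularity where somatic ratios
shrink toward 0, should lower `call_threshold_log2`.

# Somatic indels

A two-step strategy (`call_somatic_indels()`):

1. **Insert filter.** Tumor fragments with inserts outside the inclusive
   interval [50, 500] bp are removed (`filter_by_insert()`). Extreme
   inserts flag mis-mapped or structurally rearranged fragments whose
   gapped alignments are unreliable indel evidence. The bounds are read as
   inclusive ("outside 50–500" excludes only <50 and >500).
2. **Candidates and the flanked normal test.** Identical indel operations
   (chromosome, position, type, length, sequence) are grouped across the
   surviving gapped reads; groups with at least `min_tumor_support = 3`
   reads become candidates (`collect_indel_candidates()` — an exact-match
   stand-in for an external candidate generator; an externally produced
   candidate list can be fed to `normal_region_test()` directly). Each
   candidate is then tested against the normal in a region extending 5 bp
   beyond both ends: it is **somatic** only if no normal read carries any
   indel operation intersecting that region *and* at least
   `min_normal_depth = 8` normal reads overlap it. Normal indel evidence
   gives `germline_or_artifact`; a clean but shallow region gives
   `low_normal_coverage` — reported, but never counted somatic, because a
   thin normal cannot certify absence.

The normal-side evidence is raw gapped reads, not re-called indels: a
germline indel at 50% allele fraction and 40x leaves ~17 gapped normal
reads in the region, so the zero-tolerance default (`max_normal_indel_reads
= 0`) is both achievable and maximally conservative. Equivalent-indel
normalization (left-alignment) beyond exact matching is out of scope; in
simulated data, identical events produce identical operations.

# Translocations

Interchromosomal rearrangements are detected from discordant pairs — reads
whose mates align to a different chromosome (`somatic_translocations()`):

1. Non-overlapping 2 kb windows count total aligned reads (individual
   reads, not pairs), discordant reads, and the histogram of mate
   chromosomes. The most common mate chromosome is the window's *highest
   hit* (ties break by reference order), and the window statistic is the
   proportion of hit-discordant reads among total aligned reads. Windows
   tile without overlap here so that the proportions can be treated as
   independent draws.
2. Within a scope — each chromosome by default — the proportions are
   modelled as draws from a common distribution and windows above
   mean + 3 SD (sample SD) are flagged (`outlier_cutoff()`). Degenerate
   scopes behave sanely: fewer than 2 windows yields no cutoff and no
   calls; zero SD flags nothing (only strictly-above windows count).
3. A flagged window also needs `min_hit_reads = 5` hit-discordant reads.
   This floor replaces the visual inspection step of manual workflows: a
   3 SD proportion cutoff alone flags near-empty windows where one or two
   stray pairs dominate the denominator.
4. The breakpoint regions are the spans of the hit-discordant reads (window
   side) and of their mates (hit-chromosome side). The mate-side span is
   restricted to the modal 2 kb mate window ± one window: a *single*
   background read whose mate happens to fall on the hit chromosome would
   otherwise stretch the region across hundreds of kb and, downstream,
   eliminate unrelated somatic calls during normal subtraction. Adjacent
   flagged windows with the same highest hit merge into one call; each
   call records support, proportion and z-score.
5. Somatic filtering calls both samples separately and removes tumor calls
   whose padded (±1 kb) regions overlap any normal call's regions
   (`subtract_normal()`).

Each true event is typically reported twice — once anchored on each
breakpoint — and both views match the same truth event in evaluation.

# The simulator

`simulate_reference()` and `simulate_pair()` generate the data regime the
detectors assume, with every spiked event recorded in a `truth_set`:

* uniform fragment placement at the configured depths; truncated-normal
  insert sizes (default 300 ± 30 bp, floored at twice the 100 bp read
  length so mates never overlap);
* diploid germline genotypes in both samples; somatic variants in the
  tumor only, observed at allele fraction VAF × cellularity (the marginal
  model of sampling reads from a mixture of tumor and normal cells at
  copy-neutral loci);
* per-base phred qualities from a normal model (default Q35 ± 4, typical
  of a modern short-read run), a configurable zero-quality fraction
  (default 1%, so the trimming rule is always exercised), and miscalls
  injected at the rate implied by each emitted quality (capped at 0.75;
  a Q0 base is nearly random);
* tumor fragment density scaled by the true copy ratio inside spiked CNV
  segments, with ratio 0 leaving no overlapping tumor fragment at all;
* clustered discordant pairs at spiked translocation breakpoints (default
  0.5 × depth pairs, enough for the 3 SD rule at default settings) plus a
  background of stray interchromosomal pairs at rate 0.001 per fragment,
  with uniformly random mate positions — emulating residual mapping
  artifacts after quality filtering;
* a single master seed driving named substreams (`substream_seed()`), so
  identical configs reproduce byte-identical records, and fragment-level
  results are identical whether or not sequences are generated.

What it does **not** emulate: GC and mappability bias, mapping ambiguity
and soft-clipping, PCR duplicates, context-dependent error profiles,
subclonal population structure, or overlapping mates. Passing recovery
tests on this generator therefore demonstrates that the detector logic is
correct under its own stated model — not that real-data error modes are
handled; on real data the conservative normal-side gates do that work.

Simulated somatic SNV VAFs in the recovery studies are drawn uniformly
from [0.3, 1]: clonal heterozygous events sit at 0.5, while
loss-of-heterozygosity and amplified events push toward 1; VAFs below 0.3
fall under the detectors' stated sensitivity floor at 40x and are out of
the recovery conditions.

# Coordinates, numerics, determinism

* All R-level coordinates are 1-based with closed intervals, matching
  IRanges and the wider Bioconductor ecosystem the package is built on;
  writers convert to 0-based half-open for BED/BEDPE/BedGraph, while VCF
  and the pileup table are 1-based. (An alternative 0-based internal
  convention was considered and rejected as a persistent source of
  off-by-one defects in R.)
* Argmin ties in the genotype caller prefer fewer non-reference alleles,
  then lexicographic order; highest-hit ties prefer reference order — all
  outputs are deterministic.
* All output writers are timestamp-free and format numbers via
  `signif(, 6)`, so identical runs produce byte-identical files (asserted
  in the test suite).
* Problem sizes used by the checks: the SNV recovery study simulates
  2 × 2 Mb at 40x with 100 somatic SNVs and 200 germline hets; copy number
  uses 2 × 1 Mb with a 40 kb ratio-2 gain and a 30 kb homozygous deletion;
  indels use 500 kb with 20 somatic and 10 germline events; translocations
  use 3 × 300 kb with two somatic and one germline event, plus twenty
  6 × 100 kb null replicates. These sizes give stable statistics (binomial
  standard errors well inside the asserted margins) at desk-scale runtime.

# Worked example

```{r example, eval = FALSE}
library(somaticpair)

chroms <- c(chr1 = 500000L, chr2 = 500000L)
spikes <- sim_spikes(chroms, seed = 42, n_germline_snvs = 30,
                     n_somatic_snvs = 20, n_somatic_indels = 5)
sim <- do.call(sim_config, c(list(chromosomes = chroms, seed = 42,
                                  cellularity = 0.6), spikes))
res <- run_pipeline(pipeline_config(out_dir = "somaticpair_demo",
                                    simulation = sim))
res$report
```

The report lists, per event class, true/false positives, false negatives
and precision/recall against the spiked truth; the output directory holds
the VCF/BED/BEDPE/BedGraph files plus the SAM alignments and the truth set.

# Known limitations

* Single tumor/normal pair; no multi-sample joint calling, no purity or
  ploidy estimation, no subclone deconvolution.
* CNV segmentation is threshold-run merging, not CBS/HMM; allele-specific
  copy number is out of scope.
* Indel candidates come from exact-match gapped-alignment grouping; long
  (>50 bp) events and assembly-based refinement are out of scope.
* Translocation breakpoints are resolved to read-cluster spans, not
  base pair junctions; intrachromosomal rearrangements are not detected.
* The SNV caller assumes diploidy everywhere; somatic calls inside CNVs
  are still made, but their allele fractions reflect the local copy state.
```
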