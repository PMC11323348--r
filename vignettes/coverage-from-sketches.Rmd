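---
title: "Estimating multi-sample contig coverage from k-mer sketches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multi-sample contig coverage from k-mer sketches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchcov)
```

## The model

`sketchcov` estimates, for every contig of an assembly and every read set
(sample) of a project, the fold coverage of that contig in that sample —
without aligning a single read. The underlying model is the standard one for
shotgun sequencing: reads land uniformly on the genomes present in a sample,
so the number of reads covering any fixed position is Poisson with mean
equal to the fold coverage. A k-mer of a contig that is genuinely present in
a sample therefore appears in the reads with a Poisson-distributed
multiplicity, and the distribution of multiplicities over the contig's
k-mers carries all the information needed for a depth estimate.

Three observations make this practical at scale:

1. **Reads are redundant.** A 3 Gbp read set from a community of a few
   hundred genomes contains each distinct k-mer dozens of times. Indexing
   the *reads* once into a k-mer → multiplicity table and querying contigs
   against it is far cheaper than aligning reads to contigs, and the n²
   structure of a multi-sample project touches each read set only once.
2. **A consistent subsample suffices.** FracMinHash keeps exactly those
   k-mers whose 64-bit hash falls below ⌊2⁶⁴/c⌋. Because the rule depends
   only on the k-mer itself, reads and contigs retain the *same* ≈1/c
   subset, and containment fractions computed on the subsample are unbiased
   estimates of the full-set fractions.
3. **Containment separates presence from absence.** Under an
   independent-substitution model, a contig at nucleotide identity *a* to
   the sequences of a sample shares a fraction ≈ *aᵏ* of its k-mers with
   them, so the containment fraction X/N inverts to an ANI estimate
   (X/N)^(1/k). Species-level presence (ANI ≥ 0.95) is decidable from a few
   hundred sampled k-mers.

## The estimators

For one contig × sample pair with matched multiplicities
c₁ … c_X (each ≥ 1; unmatched k-mers are *not* included — their implicit
multiplicity 0 never enters any statistic) and M = median(cᵢ):

* **M ≤ 3 (`poisson`).** At low coverage the observed counts are severely
  zero-truncated: the mean of the matched counts alone would overestimate
  λ badly (the mean of a zero-truncated Poisson(0.4) is ≈ 1.2). The ratio
  estimator λ̂ = 2·N₂/N₁ built from the singleton and doubleton bins uses
  the Poisson identity P(2)/P(1) = λ/2 and is unaffected by the truncation,
  because the truncation cancels in the ratio. When no singletons exist
  (N₁ = 0, only possible at the upper edge of this regime), the mean of the
  counts is a serviceable fallback.
* **3 < M ≤ 15 (`robust_mean`).** Here truncation bias is negligible but
  repeats, conserved regions and mobile elements inflate the right tail.
  The estimator discards the largest ⌈0.1·X⌉ counts and averages the rest.
  The 10% fraction mirrors the variance computation's 90th-percentile trim;
  it costs a predictable few percent of downward bias on a clean Poisson
  (the top decile of a Poisson carries more than a tenth of the mass above
  the mean) in exchange for insensitivity to tail contamination.
* **M > 15 (`median`).** At high coverage the median is a stable,
  outlier-immune location estimate and the cheapest of the three.

The spec-level regime boundaries are stated for integer medians; an
even-sized count list can have a half-integer median (e.g. 3.5), which the
package resolves as M ≤ 3 → poisson, 3 < M ≤ 15 → robust mean, M > 15 →
median, so every nonempty count list falls in exactly one regime. Medians of
even-sized lists are the mean of the two middle order statistics.

### From k-mer multiplicity to per-base fold coverage

A k-mer at a fixed position is contained in a read of length L only if the
read starts within the L − k + 1 positions covering it, so its expected
multiplicity is λ·(L − k + 1)/L, not λ. With the defaults (k = 31,
L = 150) the raw k-mer-level estimate would understate per-base coverage by
a factor of 0.8. Since the depth file this package writes reports per-base
fold coverage (the scale alignment-based pipelines produce), the k-mer
estimate is multiplied by L̄/(L̄ − k + 1), where L̄ = total bases / total
reads recorded in the sample sketch. The correction assumes reads are not
much shorter than k (it is skipped when L̄ ≤ k) and uses the mean read
length, which is exact for constant-length short reads and a good
approximation otherwise. `coverage_for_pair(..., read_length_correct =
FALSE)` exposes the raw k-mer scale; the `depth_kmer` field always carries
it.

### Variance

Binners such as MetaBAT2 consume a per-sample variance alongside the depth.
It is computed as the unbiased sample variance of the matched (non-zero)
multiplicities after trimming below the 10th and above the 90th percentile,
which removes long-tailed outliers from mobile elements. With sorted counts,
ranks ⌊0.1·n⌋ + 1 through ⌈0.9·n⌉ are kept — for n = 10 exactly ranks
2–9, i.e. both extreme values are dropped; fewer than two survivors give
variance 0. This rank rule was chosen over textbook nearest-rank percentile
bounds because the latter would keep the minimum value whenever n ≤ 10 and
defeat the trim for short contigs. The variance is reported on the
multiplicity scale and is not read-length rescaled.

### Presence thresholds

Both gates must pass before any depth is computed:

* `min_kmers = 8` matched k-mers: below this, the containment fraction is
  too noisy to mean anything.
* `min_ani = 0.95`: the conventional species boundary. A contig failing
  either gate is reported with depth 0 and variance 0 — this is a *feature*
  of the coverage profile (absence is informative for binning), and is also
  applied to contigs that have no sampled k-mers at all (shorter than k, or
  unlucky subsampling at high c), so every contig always gets a row.

An optional coverage-adjusted ANI divides the containment by the Poisson
detection probability 1 − e^(−λ̂) (clamped at 1) before taking the k-th
root, compensating for k-mers missing purely because coverage is low rather
than because the contig diverges. It is off by default
(`ani_adjust = FALSE`): the unadjusted estimator is the better-characterized
choice, already calls presence correctly at fold coverage 0.5 under the
default thresholds, and the adjustment only matters below that.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `k` | 31 | bases | long enough that random 31-mer collisions are negligible against genome-scale k-mer sets; species-level containment convention; must be odd (a k-mer never equals its own reverse complement) and ≤ 31 (2-bit packing in 64 bits) |
| `c` | 50 | — | keeps ≈1/50 of k-mers: ≈1000 sampled k-mers for a 50 kb contig, enough for depth and ANI estimates, at 1/50 of the memory |
| `hash_seed` | 7171 | — | fixes the sampled subset; sketches with different seeds are incomparable and every comparison verifies it |
| `min_kmers` | 8 | k-mers | minimum evidence for a containment estimate |
| `min_ani` | 0.95 | fraction | species-level presence boundary |
| `read_length_correct` | TRUE | — | report per-base coverage rather than k-mer coverage |

`c` trades precision for speed/memory: the relative sampling error of the
containment fraction scales as √(c/N·contig-length). For contigs near the
1500 bp binning cutoff, c = 50 leaves ~30 sampled k-mers; depth estimates
on such contigs are noisy, which is inherent to sketching, not fixable by
the estimator.

## What the simulator emulates — and what it does not

The synthetic-data generator draws uniform-composition genomes, mutates
strain variants by independent per-site substitution, and places constant-
length reads uniformly on a circularized genome with i.i.d. substitution
errors (default 0.1%, a realistic short-read error floor). This yields
exactly the Poisson coverage and aᵏ k-mer-survival behavior the estimators
assume, which is the point: tests verify the estimators against the model
they implement, with known ground truth.

Real data deviate in ways the simulator deliberately omits: GC-biased and
otherwise non-uniform coverage, PCR duplicates, indel errors, repeats and
shared genes between community members, strain mixtures, and chimeric or
misassembled contigs. Passing tests therefore demonstrate correctness of
the estimators under their stated model and exact agreement with
brute-force counting — not field accuracy on real communities, which is a
property claim this package does not make. The linear genome ends are the
one place the simulator departs from real libraries: reads wrap around the
circularized genome, so simulated coverage has no edge decay.

Read deduplication is not performed anywhere: reads are counted as given.

## Numerical and design choices

* **Keep-rule**: strict inequality against ⌊2⁶⁴/c⌋, computed exactly in
  unsigned 64-bit arithmetic (including the c-divides-2⁶⁴ case); c = 1
  keeps everything, which is what the exact-counting oracle tests rely on.
* **Hashing**: the canonical k-mer (numeric minimum of the 2-bit packed
  forward and reverse-complement encodings, identical to the lexicographic
  rule for A<C<G<T) is mixed with the MurmurHash3 64-bit finalizer XORed
  with the seed. The finalizer is bijective and passes standard uniformity
  tests; portability and determinism are what matter here.
* **Ambiguous bases** invalidate only the windows containing them; scanning
  resumes at the next all-ACGT window, matching standard k-mer counters.
* **Sketch containers** are little-endian, magic-tagged and versioned;
  loads are all-or-nothing and a version mismatch names both versions.
  Hash tables are stored sorted, which makes sketches independent of read
  order and file partition, byte-reproducible, and mergeable by
  two-pointer intersection at query time.
* **Empty inputs**: an empty read file yields a valid empty sketch plus a
  warning; every contig × empty-sample pair is then absent/0.
* **Parallelism** is a scheduling hint (`threads`); per-sample query tasks
  are independent and results are asserted identical for any worker count.
* **Ordering contract**: depth-file rows follow assembly FASTA order,
  columns follow sample input order; number rendering is fixed at 6
  significant digits with trailing zeros trimmed, so identical runs produce
  byte-identical files.

## Problem sizes used in the validation suite

The test and acceptance computations use 10–50 kb genomes, 150 bp reads,
fold coverages between 0.5 and 50, 1/50 subsampling, and a 4-genome ×
3-sample community with 10 kb contig fragments — sizes at which estimator
error bands (15% relative, 0.2 absolute at λ ≤ 1, ANI ± 0.01) are
comfortably resolvable from seeded replicates while the whole suite runs in
well under a minute. Scaling beyond this (real assemblies with thousands of
contigs, gigabase read sets) changes constants, not behavior: every
operation is linear in its input except the per-pair query, which is linear
in the contig's sampled k-mers.

## Known limitations

* Sketch-based depth is approximate; at 1/50 subsampling short contigs get
  noisy estimates, and absence calls below the ANI threshold produce
  0-coverage dropouts that alignment pipelines would report as low non-zero
  coverage.
* The containment gate assumes species-collapsed assemblies. For
  strain-resolved assemblies (e.g. PacBio HiFi), near-identical strains all
  pass the 0.95 gate and their k-mers pool, so per-strain coverage is not
  recovered; raising `min_ani` is possible but untested territory.
* k ≤ 31 by construction; longer k would need a wider packing.
* No indel error model in the simulator, and no BAM output — binners that
  require alignments cannot consume these results.
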