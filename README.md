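# sketchcov

Alignment-free multi-sample contig coverage for metagenomic binning.

## The problem

Metagenomic binners (MetaBAT2, MaxBin2, SemiBin2, ...) group assembled
contigs into genome bins using, among other signals, each contig's read
depth across many related samples: contigs from the same genome rise and
fall together across samples. The standard way to obtain those depths is to
align every sample's reads against every assembly — for *n* samples and *n*
assemblies that is *n²* alignment runs, which quickly becomes the dominant
cost of a multi-sample binning project.

`sketchcov` replaces the alignments with k-mer containment queries. Each
sample's reads are scanned **once** into a FracMinHash-subsampled table
mapping canonical k-mer → multiplicity. Each contig's sampled k-mers are
then looked up in every sample's table — a cheap operation — so the n²
comparisons cost almost nothing beyond the n linear read passes.

## The method

For sketch parameters *k* (k-mer length, default 31) and *c* (subsampling
denominator, default 50), a k-mer is kept iff the 64-bit hash of its
canonical form falls below ⌊2⁶⁴/c⌋, so reads and contigs consistently sample
the same ≈1/c fraction of k-mer space.

For a contig with *N* sampled k-mers of which *X* are found in a sample:

- **Presence.** The containment ANI `(X/N)^(1/k)` estimates the nucleotide
  identity between the contig and the sample's sequences. If `X < 8` or
  ANI < 0.95 (the species boundary), the contig is called absent and gets
  depth 0.
- **Depth.** Let *M* be the median multiplicity of the matched k-mers.
  Depth is estimated by a three-regime estimator: a Poisson
  singleton/doubleton ratio estimator `λ̂ = 2·N₂/N₁` when `M ≤ 3`, a top-10%
  trimmed mean when `3 < M ≤ 15`, and the median itself when `M > 15`. The
  k-mer-level estimate is rescaled by `L̄/(L̄−k+1)` (mean read length `L̄`) to
  the per-base fold-coverage scale that depth files report.
- **Variance.** The sample variance of the matched multiplicities after
  10/90-percentile trimming, as used by binners such as MetaBAT2.

Output is a `jgi_summarize_bam_contig_depths`-layout TSV
(`contigName contigLen totalAvgDepth <s1> <s1>-var ...`), directly usable by
MetaBAT2 and SemiBin2, or MaxBin2-style per-sample abundance files.

A seeded simulator (`generate_genome()`, `mutate_genome()`,
`simulate_reads()`, `build_community()`) generates genomes, strain variants
at controlled identity, and Poisson-coverage read sets so the whole pipeline
is testable without any external data.

## Worked example

Two genomes in two samples: genome1 sequenced at 12× and 2×, genome2 at 0×
and 8×.

```r
library(sketchcov)
ab <- matrix(c(12, 2,
                0, 8), nrow = 2, byrow = TRUE)
spec <- community_spec(ab, genome_length = 40000, fragment_bp = 20000, seed = 11)
cm <- build_community(spec, "demo")
run_coverage(as.list(unname(cm$sample_fastqs)), cm$contigs_fasta,
             out_dir = "demo/depths")
#> assembly 'contigs': 4 contigs x 2 samples; fraction absent per sample: sample1=0.50 sample2=0.00
```

`demo/depths/contigs.depth.tsv` then contains:

```text
contigName	contigLen	totalAvgDepth	sample1	sample1-var	sample2	sample2-var
genome1_c1	20000	6.32017	10.5742	5.02274	2.06612	0.619774
genome1_c2	20000	6.56355	11.0471	4.21982	2.08	0.571586
genome2_c1	20000	3.63929	0	0	7.27857	3.93
genome2_c2	20000	3.62634	0	0	7.25267	3.78013
```

genome1's fragments read ≈10.6–11× in sample 1 and ≈2.1× in sample 2;
genome2's fragments are correctly called absent (depth 0) in sample 1 and
≈7.3× in sample 2. The depth columns are the multi-sample profile a binner
clusters on; the `-var` columns are the trimmed multiplicity variances.
Estimates at 1/50 subsampling carry a few percent of sampling noise — they
are approximate coverages intended for binning, not exact alignment depths.

The same pipeline is available from a shell via the thin CLI:

```sh
Rscript inst/cli/sketchcov.R coverage \
  --samples demo/sample1.fastq,demo/sample2.fastq \
  --assemblies demo/contigs.fa -o demo/depths
```

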