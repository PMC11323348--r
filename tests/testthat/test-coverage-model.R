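test_that("k-mer matching returns multiplicities of exactly the shared hashes", {
  p <- sketch_params(k = 31, c = 1)
  g <- generate_genome(20000, seed = 101)
  pair <- sketch_pair(g, coverage = 8, params = p, seed = 102)
  m <- match_kmers(pair$contig, pair$sample)
  expect_identical(m$n_total, length(pair$contig$hashes) %/% 8L)

  # oracle: per-k-mer read occurrence counts for every contig k-mer
  reads <- simulate_reads(g, coverage = 8, read_length = 150, seed = 102)
  want <- oracle_counts_by_hash(reads, p)
  chex <- contig_hashes(pair$contig)
  want_counts <- unname(want[chex[chex %in% names(want)]])
  expect_identical(m$counts, want_counts)
  expect_identical(m$n_matched, length(want_counts))

  # disjoint contig: no matches
  other <- sketch_pair(generate_genome(5000, seed = 103), 1, p, seed = 104)
  m2 <- match_kmers(other$contig, pair$sample)
  expect_identical(m2$n_matched, 0L)
  expect_identical(m2$counts, integer(0))
})

test_that("self-containment at c=1 matches every sampled k-mer", {
  p <- sketch_params(k = 21, c = 1)
  g <- generate_genome(8000, seed = 111)
  fq <- write_fastq_fixture(g) # the genome itself as one "read"
  sk <- sketch_reads(fq, p)
  fa <- write_fasta_fixture(c(ctg = g))
  ct <- sketch_contigs(fa, p)$contigs[[1L]]
  m <- match_kmers(ct, sk)
  expect_identical(m$n_matched, m$n_total)
  unlink(c(fq, fa))
})

test_that("matching refuses sketches built under different parameters", {
  g <- generate_genome(2000, seed = 121)
  fa <- write_fasta_fixture(c(ctg = g))
  fq <- write_fastq_fixture(substr(g, 1, 500))
  ct <- sketch_contigs(fa, sketch_params(k = 31, c = 1))$contigs[[1L]]
  sk21 <- sketch_reads(fq, sketch_params(k = 21, c = 1))
  expect_error(match_kmers(ct, sk21), "mismatch")
  sk_seed <- sketch_reads(fq, sketch_params(k = 31, c = 1, hash_seed = 1L))
  expect_error(match_kmers(ct, sk_seed), "mismatch")
  unlink(c(fa, fq))
})

test_that("containment ANI follows the k-th root closed form", {
  expect_equal(containment_ani(1000, 1000, k = 31), 1.0)
  expect_equal(containment_ani(0, 1000, k = 31), 0.0)
  expect_equal(containment_ani(0, 0, k = 31), 0.0) # N=0 defined as absent
  expect_equal(containment_ani(500, 1000, k = 31), 0.5^(1 / 31),
               tolerance = 1e-12)
  expect_equal(containment_ani(500, 1000, k = 31), 0.9779, tolerance = 1e-4)

  # coverage adjustment divides containment by 1 - exp(-lambda), clamped
  expect_equal(containment_ani(500, 1000, k = 31, lambda_hat = 0.5),
               min(1, 0.5 / (1 - exp(-0.5)))^(1 / 31), tolerance = 1e-12)
  expect_equal(containment_ani(900, 1000, k = 31, lambda_hat = 20),
               (0.9 / (1 - exp(-20)))^(1 / 31), tolerance = 1e-12)
  expect_equal(containment_ani(1000, 1000, k = 31, lambda_hat = 0.1), 1.0)
})

test_that("ANI estimate recovers the identity of a mutated contig", {
  p <- sketch_params(k = 31, c = 1)
  g <- generate_genome(20000, seed = 131)
  reads <- simulate_reads(g, coverage = 20, read_length = 150, seed = 132)
  fq <- write_fastq_fixture(reads)
  sk <- sketch_reads(fq, p)
  mut <- mutate_genome(g, 0.98, seed = 133)
  fa <- write_fasta_fixture(c(mut = mut$sequence))
  ct <- sketch_contigs(fa, p)$contigs[[1L]]
  q <- query_containment(ct, sk)
  expect_equal(q$ani, 0.98, tolerance = 0.005)
  unlink(c(fq, fa))
})

test_that("Poisson ratio estimator matches hand values and zero-truncated draws", {
  expect_equal(estimate_lambda(c(1, 1, 1, 1, 2, 2)), 1.0) # N1=4, N2=2
  expect_equal(estimate_lambda(c(5, 5, 5)), 5.0)          # fallback mean
  expect_true(is.na(estimate_lambda(integer(0))))

  # Monte-Carlo: zero-truncated Poisson(1.5) draws
  for (s in 1:20) {
    set.seed(1400 + s)
    x <- rpois(30000, 1.5)
    x <- x[x > 0][1:10000]
    expect_equal(estimate_lambda(x), 1.5, tolerance = 0.1)
  }
})

test_that("effective coverage selects the regime dictated by the median", {
  e <- effective_coverage(rep(20, 50))
  expect_identical(e$regime, "median")
  expect_equal(e$depth, 20)

  e <- effective_coverage(c(rep(5, 9), 100)) # M=5, trim ceil(1)=1 top value
  expect_identical(e$regime, "robust_mean")
  expect_equal(e$depth, 5)
  expect_equal(e$M, 5)

  e <- effective_coverage(c(1, 1, 1, 1, 2, 2)) # M=1
  expect_identical(e$regime, "poisson")
  expect_equal(e$depth, 1.0)

  # boundary coverage on both sides of M=3/4 and M=15/16
  expect_identical(effective_coverage(rep(3, 4))$regime, "poisson")
  expect_identical(effective_coverage(c(3, 4))$regime, "robust_mean") # M=3.5
  expect_identical(effective_coverage(rep(4, 4))$regime, "robust_mean")
  expect_identical(effective_coverage(rep(15, 4))$regime, "robust_mean")
  expect_identical(effective_coverage(c(15, 16))$regime, "median") # M=15.5
  expect_identical(effective_coverage(rep(16, 4))$regime, "median")

  # exactly one regime for any nonempty counts
  set.seed(15)
  for (i in 1:50) {
    x <- rpois(sample(1:40, 1), runif(1, 0.5, 40)) + 1L
    expect_true(effective_coverage(x)$regime %in%
                  c("poisson", "robust_mean", "median"))
  }
})

test_that("trimmed variance drops the tails and degenerates to zero", {
  expect_equal(coverage_variance(rep(7, 30)), 0)
  expect_equal(coverage_variance(c(1, rep(10, 8), 100)), 0) # tails trimmed
  expect_equal(coverage_variance(5L), 0)                    # single k-mer
  expect_equal(coverage_variance(c(2, 4)), var(c(2, 4)))    # small n keeps all
  x <- c(1, 3, 3, 4, 4, 4, 5, 5, 6, 50)
  expect_equal(coverage_variance(x), var(c(3, 3, 4, 4, 4, 5, 5, 6)))
})

test_that("presence gating needs both 8 matched k-mers and 95% ANI", {
  p <- sketch_params(k = 31, c = 1)
  # a 50 bp contig has 20 k-mers; sample reads covering exactly 7 or 8 of them
  g <- generate_genome(50, seed = 151)
  expect_identical(length(oracle_kmer_counts(g, 31)), 20L) # all distinct
  fa <- write_fasta_fixture(c(ctg = g))
  ct <- sketch_contigs(fa, p)$contigs[[1L]]

  fq7 <- write_fastq_fixture(substr(g, 1, 37)) # 7 k-mer windows
  fq8 <- write_fastq_fixture(substr(g, 1, 38)) # 8 k-mer windows
  sk7 <- sketch_reads(fq7, p)
  sk8 <- sketch_reads(fq8, p)
  expect_identical(sk7$n_kmers_sampled, 7L)
  expect_identical(sk8$n_kmers_sampled, 8L)

  est7 <- coverage_for_pair(ct, sk7)
  expect_identical(est7$regime, "absent")
  expect_identical(est7$n_matched, 7L)
  expect_equal(est7$depth, 0)
  expect_equal(est7$variance, 0)

  est8 <- coverage_for_pair(ct, sk8)
  expect_gte(est8$ani, 0.95) # (8/20)^(1/31) ~ 0.971
  expect_false(est8$regime == "absent")
  expect_true(query_containment(ct, sk8)$present)
  expect_false(query_containment(ct, sk7)$present)

  # enough matched k-mers but ANI below a raised threshold -> still absent
  expect_identical(
    coverage_for_pair(ct, sk8, query_thresholds(min_ani = 0.98))$regime,
    "absent")
  unlink(c(fa, fq7, fq8))
})

test_that("raising thresholds never turns an absent call into present", {
  p <- sketch_params(k = 31, c = 1)
  g <- generate_genome(5000, seed = 161)
  pair <- sketch_pair(g, coverage = 2, params = p, seed = 162)
  mut <- mutate_genome(g, 0.96, seed = 163)
  fa <- write_fasta_fixture(c(mut = mut$sequence))
  ctm <- sketch_contigs(fa, p)$contigs[[1L]]
  grid <- expand.grid(min_kmers = c(1, 8, 50, 500),
                      min_ani = c(0.8, 0.9, 0.95, 0.99))
  for (ct in list(pair$contig, ctm)) {
    prev <- NULL
    for (i in order(grid$min_kmers, grid$min_ani)) {
      q <- query_containment(ct, pair$sample,
                             query_thresholds(grid$min_kmers[i], grid$min_ani[i]))
      expect_type(q$present, "logical")
    }
    # monotone in each threshold separately
    for (mk in c(1, 8, 50)) {
      p1 <- query_containment(ct, pair$sample, query_thresholds(mk, 0.90))$present
      p2 <- query_containment(ct, pair$sample, query_thresholds(mk, 0.97))$present
      expect_true(p1 >= p2)
    }
    for (ma in c(0.85, 0.95)) {
      p1 <- query_containment(ct, pair$sample, query_thresholds(1, ma))$present
      p2 <- query_containment(ct, pair$sample, query_thresholds(10000, ma))$present
      expect_true(p1 >= p2)
    }
  }
  unlink(fa)
})

test_that("a contig sharing nothing with a sample gets depth and variance 0", {
  p <- sketch_params() # defaults k=31, c=50
  g1 <- generate_genome(50000, seed = 171)
  g2 <- generate_genome(50000, seed = 172)
  pair <- sketch_pair(g1, coverage = 10, params = p, seed = 173)
  fa <- write_fasta_fixture(c(unrelated = g2))
  ct2 <- sketch_contigs(fa, p)$contigs[[1L]]
  est <- coverage_for_pair(ct2, pair$sample)
  expect_identical(est$regime, "absent")
  expect_identical(est$depth, 0)
  expect_identical(est$variance, 0)
  # a contig with zero sampled k-mers is absent everywhere too
  tiny <- write_fasta_fixture(c(tiny = "ACGTACGT"))
  ct3 <- sketch_contigs(tiny, p)$contigs[[1L]]
  expect_identical(coverage_for_pair(ct3, pair$sample)$regime, "absent")
  unlink(c(fa, tiny))
})

test_that("depth estimates track simulated coverage with the right regimes", {
  p <- sketch_params()
  for (lam in c(1, 10)) {
    depths <- regimes <- c()
    for (s in 1:5) {
      g <- generate_genome(50000, seed = 1800 + s)
      pair <- sketch_pair(g, lam, p, seed = 1900 + 10 * lam + s,
                          error_rate = 0.001)
      est <- coverage_for_pair(pair$contig, pair$sample)
      depths <- c(depths, est$depth)
      regimes <- c(regimes, est$regime)
    }
    if (lam == 1) {
      expect_lt(abs(median(depths) - 1), 0.2)
      expect_true(all(regimes == "poisson"))
    } else {
      expect_lt(abs(median(depths) - 10) / 10, 0.15)
      expect_true(all(regimes == "robust_mean"))
    }
  }
})
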