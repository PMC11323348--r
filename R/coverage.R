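#' Presence thresholds for contig queries
#'
#' A contig is called present in a sample only if at least `min_kmers` of its
#' sampled k-mers are found in the sample's table *and* the containment ANI is
#' at least `min_ani`. Otherwise its depth is reported as 0. The 0.95 default
#' corresponds to the species-level ANI boundary commonly used in practice;
#' raising it towards strain level reduces multi-sample sensitivity.
#'
#' @param min_kmers Minimum matched k-mers (default 8).
#' @param min_ani Presence/absence containment-ANI threshold as a fraction in
#'   (0, 1] (default 0.95).
#' @return An object of class `query_thresholds`.
#' @export
query_thresholds <- function(min_kmers = 8L, min_ani = 0.95) {
  min_kmers <- as.integer(min_kmers)
  if (is.na(min_kmers) || min_kmers < 1L)
    stop("min_kmers must be a positive integer", call. = FALSE)
  if (!is.numeric(min_ani) || min_ani <= 0 || min_ani > 1)
    stop("min_ani must be in (0, 1]", call. = FALSE)
  structure(list(min_kmers = min_kmers, min_ani = as.double(min_ani)),
            class = "query_thresholds")
}

#' Match a contig's sampled k-mers against a sample's count table
#'
#' @param contig A `contig_sketch`.
#' @param sample A `sample_sketch` built with identical [sketch_params()]
#'   (enforced; comparing sketches with different k, c or hash seed is
#'   meaningless).
#' @return List with `n_total` (number of sampled contig k-mers, N),
#'   `n_matched` (how many were found, X) and `counts` (the multiplicities of
#'   exactly the matched k-mers; unmatched k-mers contribute nothing).
#' @export
match_kmers <- function(contig, sample) {
  stopifnot(inherits(contig, "contig_sketch"), inherits(sample, "sample_sketch"))
  if (!is.null(attr(contig, "params"))) stop_if_params_differ(attr(contig, "params"), sample$params)
  counts <- cpp_match_counts(contig$hashes, sample$hashes, sample$counts)
  list(n_total = length(contig$hashes) %/% 8L,
       n_matched = length(counts),
       counts = counts)
}

#' Containment ANI from matched k-mer fractions
#'
#' Estimates the average nucleotide identity of a contig to the sequences in
#' a metagenomic sample from the fraction of its sampled k-mers contained in
#' the sample: under an independent-substitution model a fraction `ani^k` of
#' k-mers survives, so `ani = (X/N)^(1/k)`. Optionally (coverage-adjusted
#' variant) the containment is first divided by the Poisson detection
#' probability `1 - exp(-lambda)` and clamped at 1, compensating for k-mers
#' missed purely because coverage is low.
#'
#' @param n_matched Matched k-mers X.
#' @param n_total Sampled contig k-mers N. `n_total = 0` yields ANI 0 (the
#'   contig is treated as absent downstream).
#' @param k K-mer length.
#' @param lambda_hat Optional Poisson coverage estimate enabling the
#'   adjustment; `NULL` (default) gives the unadjusted estimate.
#' @return ANI as a fraction in \[0, 1\].
#' @examples
#' containment_ani(500, 1000, k = 31) # ~0.978
#' @export
containment_ani <- function(n_matched, n_total, k, lambda_hat = NULL) {
  if (n_total < 1L) return(0)
  cont <- n_matched / n_total
  if (!is.null(lambda_hat) && is.finite(lambda_hat) && lambda_hat > 0) {
    det <- 1 - exp(-lambda_hat)
    if (det > 0) cont <- min(1, cont / det)
  }
  min(1, max(0, cont))^(1 / k)
}

#' Poisson coverage estimate from low-multiplicity k-mer counts
#'
#' Ratio estimator exploiting the Poisson identity P(2)/P(1) = lambda/2: with
#' N1 singleton and N2 doubleton multiplicities among the matched k-mers,
#' `lambda_hat = 2 * N2 / N1`. The ratio is unaffected by the zero-truncation
#' of the observed counts (unmatched k-mers are unobserved), which is what
#' makes it the right tool at low coverage. If no singletons exist the mean
#' of the counts is returned as a fallback.
#'
#' @param counts Integer vector of matched k-mer multiplicities (all >= 1).
#' @return Non-negative estimate, or `NA_real_` for empty input.
#' @export
estimate_lambda <- function(counts) {
  if (length(counts) == 0L) return(NA_real_)
  n1 <- sum(counts == 1L)
  n2 <- sum(counts == 2L)
  if (n1 > 0L) 2 * n2 / n1 else mean(counts)
}

#' Three-regime effective coverage from k-mer multiplicities
#'
#' Let `M` be the median multiplicity of the contig's matched k-mers in the
#' sample. Depth is estimated by the regime suited to that coverage level:
#' * `M <= 3` (*poisson*): the [estimate_lambda()] ratio estimator — at low
#'   coverage the singleton/doubleton ratio is far less biased than the mean
#'   of zero-truncated counts;
#' * `3 < M <= 15` (*robust_mean*): mean after discarding the largest
#'   `ceiling(0.1 * n)` counts, suppressing repeat/mobile-element inflation;
#' * `M > 15` (*median*): the median itself, which is stable once coverage is
#'   high.
#'
#' The estimate is on the k-mer multiplicity scale; [coverage_for_pair()]
#' rescales it to per-base fold coverage using the sample's mean read length.
#'
#' @param counts Nonempty integer vector of matched multiplicities.
#' @return List with `depth`, `regime` (one of `"poisson"`, `"robust_mean"`,
#'   `"median"`) and `M`.
#' @export
effective_coverage <- function(counts) {
  if (length(counts) == 0L)
    stop("effective_coverage() requires nonempty counts", call. = FALSE)
  M <- median(counts)
  if (M <= 3) {
    list(depth = estimate_lambda(counts), regime = "poisson", M = M)
  } else if (M <= 15) {
    n_drop <- ceiling(0.1 * length(counts))
    kept <- sort(counts)[seq_len(max(0L, length(counts) - n_drop))]
    d <- if (length(kept) > 0L) mean(kept) else mean(counts)
    list(depth = d, regime = "robust_mean", M = M)
  } else {
    list(depth = as.double(M), regime = "median", M = M)
  }
}

#' Trimmed variance of k-mer multiplicities
#'
#' Unbiased sample variance of the matched (non-zero) multiplicities after
#' trimming the values below the 10th and above the 90th percentile, removing
#' the long-tailed outliers that mobile elements and repeats produce. With the
#' sorted counts, values from rank `floor(0.1 n) + 1` through `ceiling(0.9 n)`
#' are kept; fewer than two survivors give variance 0.
#'
#' @param counts Nonempty integer vector of matched multiplicities.
#' @return Non-negative variance on the multiplicity scale.
#' @export
coverage_variance <- function(counts) {
  n <- length(counts)
  if (n == 0L)
    stop("coverage_variance() requires nonempty counts", call. = FALSE)
  s <- sort(counts)
  lo <- s[floor(0.1 * n) + 1L]
  hi <- s[ceiling(0.9 * n)]
  kept <- counts[counts >= lo & counts <= hi]
  if (length(kept) < 2L) return(0)
  var(kept)
}

#' Containment query for one contig x sample pair
#'
#' Runs the match, the Poisson coverage estimate and the containment-ANI
#' computation and applies the presence thresholds. A contig with fewer than
#' `min_kmers` matches, or with ANI below `min_ani`, is assumed absent from
#' the sample at species level.
#'
#' @inheritParams match_kmers
#' @param thresholds A [query_thresholds()] object.
#' @param ani_adjust Use the coverage-adjusted containment (divide by the
#'   Poisson detection probability before the k-th root). Default `FALSE`.
#' @return List of class `containment_result`: `n_total`, `n_matched`,
#'   `counts`, `lambda_hat`, `ani`, `present`.
#' @export
query_containment <- function(contig, sample,
                              thresholds = query_thresholds(),
                              ani_adjust = FALSE) {
  m <- match_kmers(contig, sample)
  lam <- estimate_lambda(m$counts)
  ani <- containment_ani(m$n_matched, m$n_total, sample$params$k,
                         lambda_hat = if (isTRUE(ani_adjust)) lam else NULL)
  present <- m$n_matched >= thresholds$min_kmers && ani >= thresholds$min_ani
  structure(
    list(n_total = m$n_total, n_matched = m$n_matched, counts = m$counts,
         lambda_hat = lam, ani = ani, present = present),
    class = "containment_result"
  )
}

#' Depth and variance for one contig in one sample
#'
#' The full per-pair computation: presence gating via [query_containment()],
#' then [effective_coverage()] and [coverage_variance()] on the matched
#' multiplicities. The k-mer-level depth is rescaled to per-base fold
#' coverage by `Lbar / (Lbar - k + 1)` (`Lbar` = the sample's mean read
#' length), since only reads starting within `Lbar - k + 1` of `Lbar`
#' positions cover a given k-mer; the variance stays on the multiplicity
#' scale. Absent contigs (including contigs with no sampled k-mers at all)
#' get depth 0, variance 0.
#'
#' @inheritParams query_containment
#' @param read_length_correct Apply the mean-read-length rescaling (default
#'   `TRUE`; disable to obtain the raw k-mer multiplicity scale).
#' @return List of class `coverage_estimate`: `depth`, `variance`, `regime`
#'   (`"absent"`, `"poisson"`, `"robust_mean"` or `"median"`), `M`,
#'   `depth_kmer` (pre-rescaling), `n_total`, `n_matched`, `ani`.
#' @export
coverage_for_pair <- function(contig, sample,
                              thresholds = query_thresholds(),
                              ani_adjust = FALSE,
                              read_length_correct = TRUE) {
  q <- query_containment(contig, sample, thresholds, ani_adjust)
  absent <- structure(
    list(depth = 0, variance = 0, regime = "absent", M = NA_real_,
         depth_kmer = 0, n_total = q$n_total, n_matched = q$n_matched,
         ani = q$ani),
    class = "coverage_estimate"
  )
  if (!q$present) return(absent)
  eff <- effective_coverage(q$counts)
  scale <- 1
  if (isTRUE(read_length_correct) && sample$n_reads > 0) {
    lbar <- sample$n_bases_processed / sample$n_reads
    if (lbar > sample$params$k) scale <- lbar / (lbar - sample$params$k + 1)
  }
  structure(
    list(depth = eff$depth * scale, variance = coverage_variance(q$counts),
         regime = eff$regime, M = eff$M, depth_kmer = eff$depth,
         n_total = q$n_total, n_matched = q$n_matched, ani = q$ani),
    class = "coverage_estimate"
  )
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("coverage_estimate: depth=%.4g var=%.4g regime=%s (matched %d/%d, ANI %.4f)\n",
              x$depth, x$variance, x$regime, x$n_matched, x$n_total, x$ani))
  invisible(x)
}
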