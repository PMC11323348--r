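#' Sketching parameters
#'
#' Parameters governing the FracMinHash k-mer subsample. A k-mer is kept iff
#' the 64-bit hash of its canonical form is below `floor(2^64 / c)`, so a
#' fraction of approximately `1/c` of all distinct k-mers is retained, and the
#' *same* k-mers are retained in every read set and every assembly sketched
#' with identical parameters. Sketches are only comparable when `k`, `c` and
#' `hash_seed` all agree; every comparison function enforces this.
#'
#' @param k K-mer length in bases. Must be odd (so a k-mer can never equal its
#'   own reverse complement) and between 3 and 31 (the canonical k-mer is
#'   packed 2 bits per base into a 64-bit word). Default 31, the conventional
#'   choice for species-level (~95% ANI) containment queries.
#' @param c Subsampling denominator; approximately `1/c` of k-mers are kept.
#'   Default 50.
#' @param hash_seed Integer seed mixed into the 64-bit k-mer hash. Sketches
#'   built with different seeds sample different k-mer subsets and must not
#'   be compared.
#' @param format_version Version tag embedded in sketch containers.
#' @return An object of class `sketch_params`.
#' @examples
#' sketch_params()
#' sketch_params(k = 21, c = 200)
#' @export
sketch_params <- function(k = 31L, c = 50L, hash_seed = 7171L,
                          format_version = 1L) {
  k <- as.integer(k)
  c <- as.integer(c)
  if (is.na(k) || k < 3L || k > 31L || k %% 2L == 0L)
    stop("k must be an odd integer between 3 and 31", call. = FALSE)
  if (is.na(c) || c < 1L)
    stop("c must be a positive integer", call. = FALSE)
  structure(
    list(k = k, c = c, hash_seed = as.integer(hash_seed),
         format_version = as.integer(format_version)),
    class = "sketch_params"
  )
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf("sketch_params: k=%d, c=%d (~1/%d k-mers kept), hash_seed=%d\n",
              x$k, x$c, x$c, x$hash_seed))
  invisible(x)
}

params_identical <- function(a, b) {
  a$k == b$k && a$c == b$c && a$hash_seed == b$hash_seed
}

stop_if_params_differ <- function(a, b) {
  if (!params_identical(a, b))
    stop(sprintf(paste0("sketch parameter mismatch: (k=%d, c=%d, seed=%d) vs ",
                        "(k=%d, c=%d, seed=%d); sketches are not comparable"),
                 a$k, a$c, a$hash_seed, b$k, b$c, b$hash_seed),
         call. = FALSE)
  invisible(TRUE)
}

#' Canonical form of k-mers
#'
#' Returns, for each input window, the lexicographically smaller of the
#' window and its reverse complement (alphabet A < C < G < T), uppercased.
#' Windows of the wrong length or containing any non-ACGT character yield
#' `NA`: ambiguous bases invalidate the window rather than the whole read.
#'
#' @param seq Character vector of nucleotide windows.
#' @param k Expected k-mer length.
#' @return Character vector of canonical k-mers, `NA` where invalid.
#' @examples
#' canonical_kmer(c("ACG", "TTT", "ANA"), k = 3)
#' @export
canonical_kmer <- function(seq, k) {
  seq <- as.character(seq)
  out <- rep(NA_character_, length(seq))
  ok <- !is.na(seq) & nchar(seq) == k & !grepl("[^ACGTacgt]", seq)
  if (any(ok)) {
    up <- toupper(seq[ok])
    rc <- chartr("ACGT", "TGCA", up)
    rc <- vapply(strsplit(rc, "", fixed = TRUE),
                 function(x) paste(rev(x), collapse = ""), character(1))
    out[ok] <- ifelse(up <= rc, up, rc)
  }
  out
}

#' FracMinHash keep-rule
#'
#' A hash is kept iff it is strictly below `floor(2^64 / c)`; with `c = 1`
#' every hash is kept. The identical rule is applied to reads and contigs so
#' both sides sample the same k-mer subset.
#'
#' @param hash Hashes as a raw vector (8 bytes per hash, little-endian) or as
#'   16-character hexadecimal strings (as returned by [kmer_hashes()]).
#' @param c Subsampling denominator.
#' @return Logical vector, one element per hash.
#' @examples
#' keep_kmer("ffffffffffffffff", c = 50)
#' keep_kmer("ffffffffffffffff", c = 1)
#' @export
keep_kmer <- function(hash, c) {
  if (is.character(hash)) hash <- cpp_hex_to_raw(hash)
  cpp_keep_hashes(hash, as.double(c))
}

#' Hash canonical k-mers
#'
#' 64-bit hash of the canonical form of each k-mer string, under the seed in
#' `params`. Mainly useful for tests and for inspecting sketches; the
#' sketching functions hash internally.
#'
#' @param kmers Character vector of k-mers.
#' @param params A [sketch_params()] object.
#' @return Character vector of 16-char lowercase hex hashes (`NA` for windows
#'   that are invalid: wrong length or non-ACGT characters). Hex strings sort
#'   in the same order as the underlying unsigned 64-bit values.
#' @export
kmer_hashes <- function(kmers, params = sketch_params()) {
  res <- cpp_hash_kmers(as.character(kmers), params$k,
                        as.double(params$hash_seed))
  hex <- cpp_hash_hex(res$hashes)
  hex[!res$valid] <- NA_character_
  hex
}

new_sample_sketch <- function(sample_name, params, hashes, counts,
                              n_bases, n_reads) {
  structure(
    list(sample_name = sample_name, params = params,
         hashes = hashes, counts = as.integer(counts),
         n_bases_processed = as.double(n_bases),
         n_reads = as.double(n_reads),
         n_kmers_sampled = length(hashes) %/% 8L),
    class = "sample_sketch"
  )
}

#' Sketch a sample's reads into a subsampled k-mer count table
#'
#' Scans every read of one metagenomic sample (all files pooled, so paired
#' mates simply both appear in `files`) and records, for each canonical k-mer
#' passing the FracMinHash keep-rule, its multiplicity across the whole
#' sample. The resulting table is the only per-sample data structure the
#' coverage stage needs, so each sample's reads are processed exactly once
#' regardless of how many assemblies are later queried.
#'
#' The table is stored hash-sorted, making the sketch independent of read
#' order and of how reads are split across files.
#'
#' @param files Character vector of FASTQ/FASTA paths (plain or gzip; format
#'   auto-detected from content) belonging to one sample.
#' @param params A [sketch_params()] object.
#' @param sample_name Label for output columns; defaults to the first file's
#'   basename with compression/format suffixes stripped.
#' @return A `sample_sketch`: the k-mer-to-multiplicity table plus
#'   `n_bases_processed`, `n_reads` and `n_kmers_sampled`.
#' @seealso [sketch_contigs()], [coverage_for_pair()], [write_sketch()]
#' @export
sketch_reads <- function(files, params = sketch_params(), sample_name = NULL) {
  files <- as.character(files)
  if (length(files) < 1L) stop("at least one read file is required", call. = FALSE)
  if (is.null(sample_name)) sample_name <- sample_name_from_path(files[[1L]])
  seqs <- character(0)
  for (f in files) {
    reads <- read_seqs(f)
    .counters$read_file_passes <- .counters$read_file_passes + 1L
    seqs <- c(seqs, as.character(reads))
  }
  if (length(seqs) == 0L)
    warning(sprintf("no reads found for sample '%s'; sketch is empty", sample_name),
            call. = FALSE)
  res <- cpp_sketch_reads(seqs, params$k, as.double(params$c),
                          as.double(params$hash_seed))
  new_sample_sketch(sample_name, params, res$hashes, res$counts,
                    res$n_bases, res$n_reads)
}

#' @export
print.sample_sketch <- function(x, ...) {
  cat(sprintf("sample_sketch '%s': %d sampled k-mers from %.0f reads (%.0f bp); k=%d, c=%d\n",
              x$sample_name, x$n_kmers_sampled, x$n_reads,
              x$n_bases_processed, x$params$k, x$params$c))
  invisible(x)
}

#' K-mer count table of a sample sketch
#'
#' @param sketch A `sample_sketch`.
#' @return Integer vector of multiplicities named by the 16-char hex hash of
#'   each sampled canonical k-mer, in ascending hash order.
#' @export
kmer_counts <- function(sketch) {
  stopifnot(inherits(sketch, "sample_sketch"))
  setNames(sketch$counts, cpp_hash_hex(sketch$hashes))
}

new_contig_sketch <- function(contig_name, length_bp, hashes, params = NULL) {
  structure(
    list(contig_name = contig_name, length_bp = as.integer(length_bp),
         hashes = hashes),
    class = "contig_sketch",
    params = params
  )
}

#' Sketch an assembly's contigs
#'
#' Records, per contig, the *distinct* sampled canonical k-mer hashes (a set,
#' unlike the multiplicity table kept for reads: coverage is defined per
#' distinct contig k-mer through its multiplicity in the reads). Contigs
#' shorter than `k` get an empty sketch and will be reported absent with
#' depth 0 downstream.
#'
#' @param fasta_path Path to a contig FASTA (plain or gzip).
#' @param params A [sketch_params()] object.
#' @param assembly_name Label; defaults to the file basename without suffixes.
#' @return An `assembly_sketch`: ordered list of `contig_sketch` objects
#'   (FASTA input order) plus the shared parameters. Duplicate contig names
#'   are an error since depth files key on the name.
#' @export
sketch_contigs <- function(fasta_path, params = sketch_params(),
                           assembly_name = NULL) {
  if (is.null(assembly_name)) assembly_name <- sample_name_from_path(fasta_path)
  recs <- read_seqs(fasta_path)
  nm <- vapply(strsplit(names(recs), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate contig name(s) in %s: %s", fasta_path,
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  lens <- Biostrings::width(recs)
  hash_list <- cpp_sketch_contigs(as.character(recs), params$k,
                                  as.double(params$c),
                                  as.double(params$hash_seed))
  contigs <- vector("list", length(recs))
  for (i in seq_along(recs))
    contigs[[i]] <- new_contig_sketch(nm[[i]], lens[[i]], hash_list[[i]], params)
  structure(
    list(assembly_name = assembly_name, params = params, contigs = contigs),
    class = "assembly_sketch"
  )
}

#' @export
print.assembly_sketch <- function(x, ...) {
  nk <- sum(vapply(x$contigs, function(ct) length(ct$hashes) %/% 8L, integer(1)))
  cat(sprintf("assembly_sketch '%s': %d contigs, %d sampled k-mers; k=%d, c=%d\n",
              x$assembly_name, length(x$contigs), nk, x$params$k, x$params$c))
  invisible(x)
}

#' Distinct sampled hashes of a contig sketch
#'
#' @param contig A `contig_sketch`.
#' @return Character vector of 16-char hex hashes in ascending order.
#' @export
contig_hashes <- function(contig) {
  stopifnot(inherits(contig, "contig_sketch"))
  cpp_hash_hex(contig$hashes)
}
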