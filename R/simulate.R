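# Seeded simulator: random genomes, strain variants at controlled identity,
# and uniformly-placed reads whose per-base depth is Poisson to good
# approximation. Everything is reproducible from (spec, seed); nothing is
# downloaded.

BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a uniform random genome
#'
#' @param length Genome length in bp.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return A single nucleotide string over ACGT.
#' @export
generate_genome <- function(length, seed) {
  stopifnot(length >= 1)
  with_seed(seed, paste(sample(BASES, length, replace = TRUE), collapse = ""))
}

#' Mutate a genome to a target nucleotide identity
#'
#' Independent per-site substitution with probability `1 - target_identity`,
#' each substitution to a uniformly chosen *different* base. Under this model
#' a fraction `identity^k` of k-mers is expected to survive intact, which is
#' what the containment-ANI estimator inverts.
#'
#' @param genome Nucleotide string.
#' @param target_identity Fraction in (0, 1]; 1 returns the genome unchanged.
#' @param seed Integer seed.
#' @return List with `sequence`, the realized `identity`, and
#'   `n_substitutions`.
#' @export
mutate_genome <- function(genome, target_identity, seed) {
  stopifnot(target_identity > 0, target_identity <= 1)
  n <- nchar(genome)
  if (target_identity == 1)
    return(list(sequence = genome, identity = 1, n_substitutions = 0L))
  with_seed(seed, {
    hit <- which(runif(n) < (1 - target_identity))
    if (length(hit) == 0L)
      return(list(sequence = genome, identity = 1, n_substitutions = 0L))
    chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
    # rotate each hit base by 1..3 positions in the ACGT cycle: always lands
    # on a different base, uniformly among the three alternatives
    idx <- match(chars[hit], BASES)
    chars[hit] <- BASES[((idx - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    list(sequence = paste(chars, collapse = ""),
         identity = 1 - length(hit) / n,
         n_substitutions = length(hit))
  })
}

# in-memory read simulation; circular genome so per-base depth is
# homogeneous Poisson(coverage) without edge dropoff
simulate_read_seqs <- function(genome, coverage, read_length, error_rate) {
  L <- nchar(genome)
  stopifnot(coverage >= 0, read_length >= 1, read_length <= L)
  n_reads <- round(coverage * L / read_length)
  if (n_reads == 0L) return(character(0))
  genome2 <- paste0(genome, substr(genome, 1L, read_length - 1L))
  starts <- sample.int(L, n_reads, replace = TRUE)
  reads <- substring(genome2, starts, starts + read_length - 1L)
  if (error_rate > 0) {
    total <- n_reads * read_length
    n_err <- rbinom(1L, total, error_rate)
    if (n_err > 0L) {
      pos <- sample(total, n_err) # distinct base slots: i.i.d. Bernoulli model
      ridx <- (pos - 1L) %/% read_length + 1L
      bpos <- (pos - 1L) %% read_length + 1L
      rot <- sample.int(3L, n_err, replace = TRUE)
      # substr<- is vectorized but last-wins on duplicate read indices, so
      # apply in rounds of unique reads
      while (length(ridx) > 0L) {
        first <- !duplicated(ridx)
        i <- ridx[first]; p <- bpos[first]
        tmp <- reads[i]
        old <- substr(tmp, p, p)
        substr(tmp, p, p) <- BASES[((match(old, BASES) - 1L + rot[first]) %% 4L) + 1L]
        reads[i] <- tmp
        ridx <- ridx[!first]; bpos <- bpos[!first]; rot <- rot[!first]
      }
    }
  }
  flip <- runif(n_reads) < 0.5
  if (any(flip)) reads[flip] <- revcomp_chr(reads[flip])
  reads
}

write_fastq <- function(reads, path, qual_char = "I", id_prefix = "read") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(reads) == 0L) { writeLines(character(0), con); return(invisible(path)) }
  qual <- vapply(nchar(reads), function(n)
    paste(rep(qual_char, n), collapse = ""), character(1))
  writeLines(as.vector(rbind(paste0("@", id_prefix, seq_along(reads)),
                             reads, "+", qual)), con)
  invisible(path)
}

write_fasta <- function(seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), con)
  invisible(path)
}

#' Simulate shotgun reads at a known coverage
#'
#' Draws `round(coverage * L / read_length)` reads with uniform start
#' positions on the circularized genome (so per-base depth is approximately
#' Poisson(`coverage`) with no edge artifacts), uniform strand, and i.i.d.
#' substitution errors. Quality characters are constant.
#'
#' @param genome Nucleotide string.
#' @param coverage Target fold coverage (>= 0).
#' @param read_length Read length in bp (<= genome length).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param fastq_path Optional output path (gzip if it ends in `.gz`).
#' @return Character vector of read sequences, invisibly when writing.
#' @export
simulate_reads <- function(genome, coverage, read_length = 150L,
                           error_rate = 0, seed = 1L, fastq_path = NULL) {
  reads <- with_seed(seed,
    simulate_read_seqs(genome, coverage, read_length, error_rate))
  if (!is.null(fastq_path)) {
    write_fastq(reads, fastq_path)
    return(invisible(reads))
  }
  reads
}

#' Specification of a synthetic multi-sample community
#'
#' @param abundance Genomes x samples matrix of true fold coverages (>= 0).
#' @param genome_length Genome length(s) in bp, recycled across genomes.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability. Default 0.001,
#'   matching the error floor of modern short-read instruments.
#' @param fragment_bp Optional contig size: genomes are cut into consecutive
#'   fragments of this length (last fragment keeps the remainder) to emulate
#'   an assembly; `NULL` leaves one contig per genome.
#' @param seed Integer master seed; every genome and sample derives its own
#'   stream from it.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(abundance, genome_length = 50000L,
                           read_length = 150L, error_rate = 0.001,
                           fragment_bp = NULL, seed = 1L) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  glen <- rep_len(as.integer(genome_length), nrow(abundance))
  if (read_length < 3L) stop("read_length too short", call. = FALSE)
  structure(
    list(n_genomes = nrow(abundance), n_samples = ncol(abundance),
         genome_length = glen, abundance = abundance,
         read_length = as.integer(read_length),
         error_rate = as.double(error_rate),
         fragment_bp = if (is.null(fragment_bp)) NULL else as.integer(fragment_bp),
         seed = as.integer(seed)),
    class = "community_spec"
  )
}

fragment_seq <- function(seq, name, fragment_bp) {
  L <- nchar(seq)
  if (is.null(fragment_bp) || L <= fragment_bp)
    return(setNames(seq, name))
  starts <- seq(1L, L, by = fragment_bp)
  starts <- starts[L - starts + 1L >= fragment_bp | starts == 1L]
  ends <- c(starts[-1L] - 1L, L)
  frags <- substring(seq, starts, ends)
  setNames(frags, paste0(name, "_c", seq_along(frags)))
}

#' Build a synthetic community fixture on disk
#'
#' Writes one contig FASTA (all genomes, optionally fragmented), one FASTQ
#' per sample pooling every genome's reads at its column abundance, and a
#' truth table of per-genome, per-sample coverage. Runs are byte-identical
#' for identical (spec, seed).
#'
#' @param spec A [community_spec()].
#' @param out_dir Output directory (created if needed).
#' @param gzip Write gzip-compressed FASTQs.
#' @return List with `contigs_fasta`, `sample_fastqs` (named by sample),
#'   `truth` (data.frame genome/contig x sample of true coverage),
#'   `contig_genome` (named vector mapping contig to source genome), and
#'   `genomes` (the sequences).
#' @export
build_community <- function(spec, out_dir, gzip = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gnames <- paste0("genome", seq_len(spec$n_genomes))
  snames <- paste0("sample", seq_len(spec$n_samples))
  seeds <- with_seed(spec$seed,
    matrix(sample.int(.Machine$integer.max,
                      spec$n_genomes * (spec$n_samples + 1L)),
           nrow = spec$n_genomes))
  genomes <- vapply(seq_len(spec$n_genomes), function(g)
    generate_genome(spec$genome_length[[g]], seeds[g, 1L]), character(1))
  names(genomes) <- gnames

  contigs <- unlist(lapply(seq_along(genomes), function(g)
    fragment_seq(genomes[[g]], gnames[[g]], spec$fragment_bp)))
  contig_genome <- setNames(sub("_c[0-9]+$", "", names(contigs)),
                            names(contigs))
  contigs_fasta <- file.path(out_dir, "contigs.fa")
  write_fasta(contigs, contigs_fasta)

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  sample_fastqs <- setNames(file.path(out_dir, paste0(snames, ext)), snames)
  for (s in seq_len(spec$n_samples)) {
    reads <- character(0)
    for (g in seq_len(spec$n_genomes)) {
      cov <- spec$abundance[g, s]
      if (cov > 0)
        reads <- c(reads, with_seed(seeds[g, s + 1L],
          simulate_read_seqs(genomes[[g]], cov, spec$read_length,
                             spec$error_rate)))
    }
    write_fastq(reads, sample_fastqs[[s]])
  }

  truth <- as.data.frame(spec$abundance)
  colnames(truth) <- snames
  rownames(truth) <- gnames
  truth_path <- file.path(out_dir, "truth_coverage.tsv")
  con <- file(truth_path, "wb")
  writeLines(c(paste(c("genome", snames), collapse = "\t"),
               paste(gnames, apply(spec$abundance, 1L, function(r)
                 paste(fmt_num(r), collapse = "\t")), sep = "\t")), con)
  close(con)

  list(contigs_fasta = contigs_fasta, sample_fastqs = sample_fastqs,
       truth = truth, truth_path = truth_path,
       contig_genome = contig_genome, genomes = genomes)
}
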