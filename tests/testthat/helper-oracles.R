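# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive canonical k-mer multiset of a set of sequences, built by plain
# window enumeration + Biostrings reverse complement (independent of the
# package's rolling 2-bit scanner). Returns a named integer vector keyed by
# canonical k-mer string.
oracle_kmer_counts <- function(seqs, k) {
  wins <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    wins <- c(wins, substring(s, 1:(n - k + 1), k:n))
  }
  wins <- wins[!grepl("[^ACGTacgt]", wins)]
  if (length(wins) == 0L) return(setNames(integer(0), character(0)))
  up <- toupper(wins)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
  canon <- ifelse(up <= rc, up, rc)
  tab <- table(canon)
  setNames(as.integer(tab), names(tab))
}

# oracle table re-keyed by the package's hex hash (hashing is the shared
# primitive; the counting/sketching pipeline under test stays independent)
oracle_counts_by_hash <- function(seqs, params) {
  tab <- oracle_kmer_counts(seqs, params$k)
  setNames(as.integer(tab), kmer_hashes(names(tab), params))
}

write_fastq_fixture <- function(reads, path = tempfile(fileext = ".fastq")) {
  lines <- as.vector(rbind(paste0("@r", seq_along(reads)), reads, "+",
                           vapply(nchar(reads),
                                  function(n) strrep("I", n), character(1))))
  writeLines(lines, path)
  path
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa")) {
  if (is.null(names(seqs))) names(seqs) <- paste0("ctg", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sketch a genome's simulated reads and its contig in one go
sketch_pair <- function(genome, coverage, params, seed,
                        read_length = 150L, error_rate = 0) {
  reads <- simulate_reads(genome, coverage, read_length, error_rate,
                          seed = seed)
  fq <- write_fastq_fixture(reads)
  on.exit(unlink(fq), add = TRUE)
  fa <- write_fasta_fixture(c(ctg = genome))
  on.exit(unlink(fa), add = TRUE)
  list(sample = sketch_reads(fq, params),
       contig = sketch_contigs(fa, params)$contigs[[1L]])
}
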