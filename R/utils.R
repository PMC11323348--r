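# shared internal helpers

# sample/assembly label from a file path: basename minus compression and
# sequence-format suffixes (mirrors the BAM-derived column names of the
# alignment-based depth script this package's output imitates)
sample_name_from_path <- function(path) {
  b <- basename(path)
  b <- sub("\\.(gz|bz2|xz)$", "", b)
  sub("\\.(fastq|fq|fasta|fa|fna)$", "", b)
}

# peek at the first non-empty character to distinguish FASTA from FASTQ;
# gzfile() transparently reads plain files too
detect_seq_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return("empty")
    if (nzchar(trimws(line))) break
  }
  ch <- substr(trimws(line), 1L, 1L)
  if (ch == ">") return("fasta")
  if (ch == "@") return("fastq")
  stop(sprintf("cannot detect sequence format of '%s' (first character '%s')",
               path, ch), call. = FALSE)
}

# read a FASTA/FASTQ file (plain or gzip) into a DNAStringSet
read_seqs <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read input file '%s': no such file", path),
         call. = FALSE)
  fmt <- detect_seq_format(path)
  if (fmt == "empty") return(Biostrings::DNAStringSet())
  Biostrings::readDNAStringSet(path, format = fmt)
}

# evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
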