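# Versioned binary sketch containers (.smsk for samples, .ctsk for
# assemblies). Layout, all little-endian:
#   magic (4 bytes "SMSK"/"CTSK"), format_version int32,
#   k int32, c int32, hash_seed int32,
#   then the type-specific payload with length-prefixed strings and tables.

SKETCH_FORMAT_VERSION <- 1L

write_str <- function(con, s) {
  r <- charToRaw(enc2utf8(s))
  writeBin(length(r), con, size = 4L, endian = "little")
  writeBin(r, con)
}

read_str <- function(con) {
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n) != 1L || is.na(n) || n < 0L) stop("corrupt sketch container: bad string length", call. = FALSE)
  rawToChar(readBin(con, "raw", n = n))
}

read_chk <- function(con, what, n, size = NA_integer_) {
  x <- readBin(con, what, n = n, size = size, endian = "little")
  if (length(x) != n)
    stop("corrupt sketch container: truncated file", call. = FALSE)
  x
}

#' Persist and load k-mer sketches
#'
#' Sketches round-trip bit-exactly: `read_sketch(write_sketch(x, p))` equals
#' `x`, including parameters and names. The container is versioned; a wrong
#' magic or an unsupported version is a hard error, never a partial load.
#'
#' @param sketch A `sample_sketch` or `assembly_sketch`.
#' @param path Output path (conventionally `.smsk` / `.ctsk`).
#' @return `write_sketch()` returns `path` invisibly; `read_sketch()` returns
#'   the stored object.
#' @export
write_sketch <- function(sketch, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (inherits(sketch, "sample_sketch")) {
    writeBin(charToRaw("SMSK"), con)
    p <- sketch$params
    writeBin(c(SKETCH_FORMAT_VERSION, p$k, p$c, p$hash_seed), con,
             size = 4L, endian = "little")
    write_str(con, sketch$sample_name)
    writeBin(c(sketch$n_bases_processed, sketch$n_reads), con,
             size = 8L, endian = "little")
    writeBin(sketch$n_kmers_sampled, con, size = 4L, endian = "little")
    writeBin(sketch$counts, con, size = 4L, endian = "little")
    writeBin(sketch$hashes, con)
  } else if (inherits(sketch, "assembly_sketch")) {
    writeBin(charToRaw("CTSK"), con)
    p <- sketch$params
    writeBin(c(SKETCH_FORMAT_VERSION, p$k, p$c, p$hash_seed), con,
             size = 4L, endian = "little")
    write_str(con, sketch$assembly_name)
    writeBin(length(sketch$contigs), con, size = 4L, endian = "little")
    for (ct in sketch$contigs) {
      write_str(con, ct$contig_name)
      writeBin(c(ct$length_bp, length(ct$hashes) %/% 8L), con,
               size = 4L, endian = "little")
      writeBin(ct$hashes, con)
    }
  } else {
    stop("write_sketch() expects a sample_sketch or assembly_sketch", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read sketch '%s': no such file", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 4L))
  if (!magic %in% c("SMSK", "CTSK"))
    stop(sprintf("'%s' is not a sketch container (bad magic bytes '%s')",
                 path, magic), call. = FALSE)
  hdr <- read_chk(con, "integer", 4L, size = 4L)
  ver <- hdr[[1L]]
  if (ver != SKETCH_FORMAT_VERSION)
    stop(sprintf("unsupported sketch format version in '%s': expected %d, found %d",
                 path, SKETCH_FORMAT_VERSION, ver), call. = FALSE)
  params <- sketch_params(k = hdr[[2L]], c = hdr[[3L]], hash_seed = hdr[[4L]],
                          format_version = ver)
  if (magic == "SMSK") {
    name <- read_str(con)
    meta <- read_chk(con, "double", 2L, size = 8L)
    n <- read_chk(con, "integer", 1L, size = 4L)
    counts <- read_chk(con, "integer", n, size = 4L)
    hashes <- read_chk(con, "raw", 8L * n)
    new_sample_sketch(name, params, hashes, counts, meta[[1L]], meta[[2L]])
  } else {
    name <- read_str(con)
    nct <- read_chk(con, "integer", 1L, size = 4L)
    contigs <- vector("list", nct)
    for (i in seq_len(nct)) {
      cname <- read_str(con)
      lens <- read_chk(con, "integer", 2L, size = 4L)
      hashes <- read_chk(con, "raw", 8L * lens[[2L]])
      contigs[[i]] <- new_contig_sketch(cname, lens[[1L]], hashes, params)
    }
    structure(list(assembly_name = name, params = params, contigs = contigs),
              class = "assembly_sketch")
  }
}
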