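#' Construct a depth matrix
#'
#' Contigs x samples table of estimated fold coverage and trimmed variance
#' for one assembly. Row order is exactly the assembly's FASTA order and
#' column order exactly the sample input order, so output files are
#' deterministic.
#'
#' @param assembly_name Assembly label.
#' @param contig_names,contig_lengths Per-contig name and length (bp).
#' @param sample_names Per-sample labels, in input order.
#' @param depth,variance Numeric matrices, contigs x samples, all entries
#'   >= 0.
#' @return An object of class `depth_matrix`.
#' @export
depth_matrix <- function(assembly_name, contig_names, contig_lengths,
                         sample_names, depth, variance) {
  depth <- as.matrix(depth)
  variance <- as.matrix(variance)
  nc <- length(contig_names)
  ns <- length(sample_names)
  if (length(contig_lengths) != nc)
    stop("contig_lengths must match contig_names", call. = FALSE)
  if (!all(dim(depth) == c(nc, ns)) || !all(dim(variance) == c(nc, ns)))
    stop("depth/variance must be contigs x samples matrices", call. = FALSE)
  if (any(depth < 0) || any(variance < 0))
    stop("depth and variance entries must be >= 0", call. = FALSE)
  if (anyDuplicated(sample_names))
    stop("sample names must be unique (output columns would be ambiguous)",
         call. = FALSE)
  dimnames(depth) <- dimnames(variance) <- list(contig_names, sample_names)
  structure(
    list(assembly_name = assembly_name,
         contig_names = as.character(contig_names),
         contig_lengths = as.numeric(contig_lengths),
         sample_names = as.character(sample_names),
         depth = depth, variance = variance),
    class = "depth_matrix"
  )
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("depth_matrix '%s': %d contigs x %d samples\n",
              x$assembly_name, length(x$contig_names), length(x$sample_names)))
  invisible(x)
}

# fixed rendering: 6 significant digits, trailing zeros trimmed (3 -> "3"),
# so files are byte-deterministic
fmt_num <- function(x) sprintf("%.6g", x)

#' Write a MetaBAT2-layout depth file
#'
#' Tab-separated table in the layout of MetaBAT2's
#' `jgi_summarize_bam_contig_depths` output: header
#' `contigName contigLen totalAvgDepth <s1> <s1>-var ...`, one row per
#' contig, `totalAvgDepth` the arithmetic mean of the contig's per-sample
#' depths. This file is also what SemiBin2 accepts as a coverage table.
#'
#' @param matrix A [depth_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabat_depth <- function(matrix, path) {
  stopifnot(inherits(matrix, "depth_matrix"))
  ns <- length(matrix$sample_names)
  header <- c("contigName", "contigLen", "totalAvgDepth",
              as.vector(rbind(matrix$sample_names,
                              paste0(matrix$sample_names, "-var"))))
  lines <- paste(header, collapse = "\t")
  if (length(matrix$contig_names) > 0L) {
    tot <- rowMeans(matrix$depth)
    body <- vapply(seq_along(matrix$contig_names), function(i) {
      vals <- as.vector(rbind(matrix$depth[i, ], matrix$variance[i, ]))
      paste(c(matrix$contig_names[[i]], sprintf("%.0f", matrix$contig_lengths[[i]]),
              fmt_num(tot[[i]]), fmt_num(vals)), collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  con <- file(path, "wb") # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a MetaBAT2-layout depth file
#'
#' Inverse of [write_metabat_depth()] up to the printed precision; nothing is
#' recomputed. The canonical layout of `3 + 2n` columns with alternating
#' `<sample>` / `<sample>-var` names is enforced.
#'
#' @param path Path to a depth file.
#' @param assembly_name Optional label; defaults to the file basename.
#' @return A [depth_matrix()].
#' @export
read_depth_file <- function(path, assembly_name = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  nm <- colnames(tab)
  if (length(nm) < 3L ||
      !identical(nm[1:3], c("contigName", "contigLen", "totalAvgDepth")))
    stop(sprintf(paste0("malformed depth header in '%s': expected columns ",
                        "contigName, contigLen, totalAvgDepth first"), path),
         call. = FALSE)
  rest <- nm[-(1:3)]
  if (length(rest) %% 2L != 0L)
    stop(sprintf(paste0("malformed depth header in '%s': odd number of ",
                        "sample columns (%d); a depth-only two-column file ",
                        "is a MaxBin2-style abundance file, not a MetaBAT2 ",
                        "depth file"), path, length(rest)), call. = FALSE)
  ns <- length(rest) %/% 2L
  snames <- rest[seq(1L, by = 2L, length.out = ns)]
  vnames <- rest[seq(2L, by = 2L, length.out = ns)]
  bad <- which(vnames != paste0(snames, "-var"))
  if (length(bad) > 0L)
    stop(sprintf("malformed depth header in '%s': column '%s' should be '%s-var'",
                 path, vnames[bad[1L]], snames[bad[1L]]), call. = FALSE)
  if (is.null(assembly_name))
    assembly_name <- sub("\\.(tsv|txt)$", "", basename(path))
  dm <- as.matrix(tab[, 3L + seq(1L, by = 2L, length.out = ns), drop = FALSE])
  vm <- as.matrix(tab[, 3L + seq(2L, by = 2L, length.out = ns), drop = FALSE])
  if (ns == 0L) dm <- vm <- matrix(0, nrow = nrow(tab), ncol = 0L)
  depth_matrix(assembly_name, tab$contigName, tab$contigLen, snames, dm, vm)
}

#' Write MaxBin2-style abundance files
#'
#' One headerless two-column file (`contig<TAB>depth`) per sample, plus a
#' tab-separated manifest (`sample<TAB>file`) listing them in sample order —
#' the form MaxBin2's `-abund_list` consumes.
#'
#' @param matrix A [depth_matrix()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the per-sample file paths, with the manifest
#'   path as attribute `"manifest"`.
#' @export
write_maxbin_abundance <- function(matrix, out_dir) {
  stopifnot(inherits(matrix, "depth_matrix"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(length(matrix$sample_names))
  for (j in seq_along(matrix$sample_names)) {
    paths[[j]] <- file.path(out_dir, paste0(matrix$assembly_name, ".",
                                            matrix$sample_names[[j]],
                                            ".abund.tsv"))
    con <- file(paths[[j]], "wb")
    writeLines(paste(matrix$contig_names, fmt_num(matrix$depth[, j]),
                     sep = "\t"), con)
    close(con)
  }
  manifest <- file.path(out_dir, paste0(matrix$assembly_name,
                                        ".abund_list.txt"))
  con <- file(manifest, "wb")
  writeLines(paste(matrix$sample_names, paths, sep = "\t"), con)
  close(con)
  attr(paths, "manifest") <- manifest
  paths
}
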