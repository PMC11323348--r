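# Orchestration: n costly read-sketching passes, then n x m cheap queries.

norm_sample_specs <- function(samples) {
  # accept a character vector (one file per sample) or a list of file
  # vectors (paired/multi-file samples), optionally named
  if (is.character(samples)) samples <- as.list(samples)
  if (!is.list(samples) || length(samples) == 0L)
    stop("at least one sample is required", call. = FALSE)
  nms <- names(samples)
  if (is.null(nms)) nms <- rep("", length(samples))
  for (i in seq_along(samples)) {
    if (!nzchar(nms[[i]]))
      nms[[i]] <- sample_name_from_path(samples[[i]][[1L]])
  }
  if (anyDuplicated(nms))
    stop(sprintf("duplicate sample name(s): %s (depth columns would be ambiguous)",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  names(samples) <- nms
  samples
}

#' Sketch read sets and assemblies to disk
#'
#' Builds one `.smsk` sketch per sample and one `.ctsk` sketch per assembly
#' under `out_dir`. Sketches that already exist and are newer than all their
#' inputs are skipped unless `force = TRUE`. Failures are reported per input
#' file; the remaining sketches are still written, then a single error names
#' everything that failed.
#'
#' @param samples Character vector of read files (one per sample) or list of
#'   file vectors (paired files pooled per sample); names override the
#'   file-derived sample names.
#' @param assemblies Character vector of contig FASTA paths.
#' @param params A [sketch_params()] object embedded in every sketch.
#' @param out_dir Output directory for sketch files.
#' @param force Rewrite sketches even when up to date.
#' @return Named list with `samples` and `assemblies`: paths of the sketch
#'   files in input order.
#' @export
sketch_inputs <- function(samples = character(), assemblies = character(),
                          params = sketch_params(), out_dir = ".",
                          force = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  samples <- if (length(samples)) norm_sample_specs(samples) else list()
  failures <- character(0)
  up_to_date <- function(out, inputs) {
    file.exists(out) && all(file.exists(inputs)) &&
      file.mtime(out) >= max(file.mtime(inputs))
  }
  spaths <- character(length(samples))
  for (i in seq_along(samples)) {
    spaths[[i]] <- file.path(out_dir, paste0(names(samples)[[i]], ".smsk"))
    if (!force && up_to_date(spaths[[i]], samples[[i]])) next
    ok <- tryCatch({
      write_sketch(sketch_reads(samples[[i]], params,
                                sample_name = names(samples)[[i]]),
                   spaths[[i]])
      TRUE
    }, error = function(e) {
      warning(sprintf("failed to sketch sample '%s': %s",
                      names(samples)[[i]], conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (!ok) failures <- c(failures, samples[[i]][[1L]])
  }
  apaths <- character(length(assemblies))
  for (i in seq_along(assemblies)) {
    aname <- sample_name_from_path(assemblies[[i]])
    apaths[[i]] <- file.path(out_dir, paste0(aname, ".ctsk"))
    if (!force && up_to_date(apaths[[i]], assemblies[[i]])) next
    ok <- tryCatch({
      write_sketch(sketch_contigs(assemblies[[i]], params,
                                  assembly_name = aname), apaths[[i]])
      TRUE
    }, error = function(e) {
      warning(sprintf("failed to sketch assembly '%s': %s",
                      assemblies[[i]], conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (!ok) failures <- c(failures, assemblies[[i]])
  }
  if (length(failures) > 0L)
    stop(sprintf("sketching failed for %d input(s): %s",
                 length(failures), paste(failures, collapse = ", ")),
         call. = FALSE)
  list(samples = spaths, assemblies = apaths)
}

#' Depth matrix for one assembly across samples
#'
#' Queries every contig of one assembly against every sample sketch and
#' assembles the contigs x samples depth/variance matrices. Row order is the
#' assembly's FASTA order, column order the sample order given.
#'
#' @param assembly An `assembly_sketch`.
#' @param samples List of `sample_sketch` objects (all sharing the assembly's
#'   [sketch_params()]; enforced before any work is done).
#' @param thresholds A [query_thresholds()] object.
#' @param ani_adjust,read_length_correct Passed to [coverage_for_pair()].
#' @param threads Worker-count hint for per-sample querying
#'   (`parallel::mclapply`); results are identical for any value.
#' @return A [depth_matrix()].
#' @export
compute_depth <- function(assembly, samples,
                          thresholds = query_thresholds(),
                          ani_adjust = FALSE, read_length_correct = TRUE,
                          threads = 1L) {
  stopifnot(inherits(assembly, "assembly_sketch"))
  if (inherits(samples, "sample_sketch")) samples <- list(samples)
  for (s in samples) stop_if_params_differ(assembly$params, s$params)
  snames <- vapply(samples, `[[`, character(1), "sample_name")
  one_sample <- function(s) {
    ests <- lapply(assembly$contigs, coverage_for_pair, sample = s,
                   thresholds = thresholds, ani_adjust = ani_adjust,
                   read_length_correct = read_length_correct)
    cbind(vapply(ests, `[[`, numeric(1), "depth"),
          vapply(ests, `[[`, numeric(1), "variance"))
  }
  cols <- if (threads > 1L) {
    parallel::mclapply(samples, one_sample, mc.cores = threads)
  } else {
    lapply(samples, one_sample)
  }
  nc <- length(assembly$contigs)
  dmat <- vapply(cols, function(x) x[, 1L], numeric(nc))
  vmat <- vapply(cols, function(x) x[, 2L], numeric(nc))
  if (nc == 1L) { dmat <- matrix(dmat, 1L); vmat <- matrix(vmat, 1L) }
  depth_matrix(assembly$assembly_name,
               vapply(assembly$contigs, `[[`, character(1), "contig_name"),
               vapply(assembly$contigs, `[[`, numeric(1), "length_bp"),
               snames, dmat, vmat)
}

#' Multi-sample coverage pipeline
#'
#' End-to-end run: sketch each sample's reads once, sketch each assembly,
#' then query all contigs of every assembly against every sample and write
#' one binner-ready depth file per assembly. This is the linear-sketch /
#' quadratic-cheap-query structure that makes multi-sample coverage
#' tractable: for n samples only n costly read passes are needed, however
#' many assemblies are queried.
#'
#' @inheritParams sketch_inputs
#' @inheritParams compute_depth
#' @param output_format `"metabat2"` (one `jgi_summarize_bam_contig_depths`-
#'   layout TSV per assembly; also accepted by SemiBin2) or `"maxbin2"`
#'   (per-sample two-column abundance files plus manifest per assembly).
#' @param out_dir Where depth files are written.
#' @param sketch_dir Optional directory for reusable on-disk sketches; when
#'   `NULL` sketches are kept in memory only.
#' @param quiet Suppress the per-assembly run summary on standard error.
#' @return Invisibly, a named list of [depth_matrix()] objects (one per
#'   assembly, in input order). Depth files are written under `out_dir` as
#'   `<assembly>.depth.tsv` (metabat2) or `<assembly>.abund/` files
#'   (maxbin2).
#' @examples
#' \dontrun{
#' run_coverage(samples = c("s1.fq.gz", "s2.fq.gz"),
#'              assemblies = c("asm1.fa", "asm2.fa"),
#'              out_dir = "depths")
#' }
#' @export
run_coverage <- function(samples, assemblies,
                         params = sketch_params(),
                         thresholds = query_thresholds(),
                         output_format = c("metabat2", "maxbin2"),
                         out_dir = ".", sketch_dir = NULL,
                         ani_adjust = FALSE, read_length_correct = TRUE,
                         threads = 1L, force = FALSE, quiet = FALSE) {
  output_format <- match.arg(output_format)
  if (length(assemblies) == 0L)
    stop("at least one assembly is required", call. = FALSE)
  samples <- norm_sample_specs(samples)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(sketch_dir)) {
    paths <- sketch_inputs(samples, assemblies, params, sketch_dir,
                           force = force)
    ssk <- lapply(paths$samples, read_sketch)
    ask <- lapply(paths$assemblies, read_sketch)
  } else {
    ssk <- lapply(seq_along(samples), function(i)
      sketch_reads(samples[[i]], params, sample_name = names(samples)[[i]]))
    ask <- lapply(assemblies, function(a)
      sketch_contigs(a, params, assembly_name = sample_name_from_path(a)))
  }
  # fail before any output if any sketch pair disagrees
  for (s in ssk) stop_if_params_differ(params, s$params)
  for (a in ask) stop_if_params_differ(params, a$params)

  out <- vector("list", length(ask))
  names(out) <- vapply(ask, `[[`, character(1), "assembly_name")
  for (i in seq_along(ask)) {
    dm <- compute_depth(ask[[i]], ssk, thresholds = thresholds,
                        ani_adjust = ani_adjust,
                        read_length_correct = read_length_correct,
                        threads = threads)
    if (output_format == "metabat2") {
      write_metabat_depth(dm, file.path(out_dir,
                                        paste0(dm$assembly_name, ".depth.tsv")))
    } else {
      write_maxbin_abundance(dm, out_dir)
    }
    if (!quiet) {
      fa <- colMeans(dm$depth == 0)
      message(sprintf("assembly '%s': %d contigs x %d samples; fraction absent per sample: %s",
                      dm$assembly_name, length(dm$contig_names),
                      length(dm$sample_names),
                      paste(sprintf("%s=%.2f", dm$sample_names, fa),
                            collapse = " ")))
    }
    out[[i]] <- dm
  }
  invisible(out)
}
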