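# End-to-end orchestration: reads/SAM -> parse -> filter -> depth -> GEQ ->
# cell fractions -> attribution -> apportionment, with a resolved run
# configuration written beside every output set.

#' Run configuration
#'
#' Collects every tunable of a pipeline run with the tuned defaults:
#' identity 93%, overlap 70%, masking 0%, LOD 0.01%, detection at >= 1
#' filtered read and breadth >= 0.
#'
#' @param min_identity minimum alignment identity, percent.
#' @param min_overlap minimum alignment-to-read overlap, percent.
#' @param masking_percent coverage masking percentage.
#' @param lod_percent limit of detection, percent relative abundance.
#' @param min_reads,min_breadth per-genome detection rule.
#' @param ags_bp average genome size for the supplied-AGS GEQ backend, or
#'   NULL to use marker coverage (requires \code{marker_coords}).
#' @param marker_coords marker coordinate table or TSV path for the
#'   marker-coverage GEQ backend.
#' @param aligner_cmd optional aligner command template with placeholders
#'   \code{\{ref\}}, \code{\{fastq\}}, \code{\{out\}}; default uses
#'   \code{bwa mem} when FASTQ input is given.
#' @return object of class \code{run_config} (a named list).
#' @export
run_config <- function(min_identity = 93, min_overlap = 70,
                       masking_percent = 0, lod_percent = 0.01,
                       min_reads = 1, min_breadth = 0,
                       ags_bp = NULL, marker_coords = NULL,
                       aligner_cmd = NULL) {
  structure(list(min_identity = min_identity, min_overlap = min_overlap,
                 masking_percent = masking_percent, lod_percent = lod_percent,
                 min_reads = min_reads, min_breadth = min_breadth,
                 ags_bp = ags_bp, marker_coords = marker_coords,
                 aligner_cmd = aligner_cmd),
            class = "run_config")
}

#' Write a run configuration as a flat key=value file
#'
#' @param config a \code{run_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  scalars <- config[!vapply(config, is.null, TRUE)]
  scalars <- scalars[vapply(scalars, function(v) is.atomic(v) && length(v) == 1L, TRUE)]
  writeLines(paste0(names(scalars), "=", vapply(scalars, format, "")), path)
  invisible(path)
}

#' Read a run configuration from a key=value file
#'
#' Unknown keys are an error; numeric values are coerced.
#'
#' @param path file written by \code{\link{write_run_config}} (or by hand).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0L) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (i in seq_along(keys)) {
    v <- vals[i]
    num <- suppressWarnings(as.numeric(v))
    cfg[[keys[i]]] <- if (!is.na(num)) num else v
  }
  cfg
}

#' Align reads to a database with an external aligner
#'
#' Thin wrapper over \code{bwa index} + \code{bwa mem} (or a user command
#' template). The database's concatenated reference FASTA is written and
#' indexed on first use.
#'
#' @param fastq path to the reads.
#' @param db a \code{source_db}.
#' @param out output SAM path (default next to the FASTQ).
#' @param ref_fasta optional pre-built reference FASTA (re-used across
#'   samples); default: written to a temporary file.
#' @param aligner_cmd optional command template with \code{\{ref\}},
#'   \code{\{fastq\}}, \code{\{out\}} placeholders; default
#'   \code{bwa mem \{ref\} \{fastq\} > \{out\}}.
#' @return the SAM path, invisibly.
#' @export
align_reads <- function(fastq, db, out = sub("\\.f(ast)?q$", ".sam", fastq),
                        ref_fasta = NULL, aligner_cmd = NULL) {
  if (is.null(ref_fasta)) {
    ref_fasta <- tempfile("dbref", fileext = ".fasta")
  }
  if (!file.exists(ref_fasta)) db_reference_fasta(db, ref_fasta)
  if (is.null(aligner_cmd)) {
    if (Sys.which("bwa") == "") stop("bwa not found on PATH; supply aligner_cmd")
    if (!file.exists(paste0(ref_fasta, ".bwt"))) {
      status <- system2("bwa", c("index", ref_fasta), stdout = FALSE, stderr = FALSE)
      if (status != 0L) stop("bwa index failed")
    }
    status <- system2("bwa", c("mem", "-v", "1", ref_fasta, fastq),
                      stdout = out, stderr = FALSE)
    if (status != 0L) stop("bwa mem failed")
  } else {
    cmd <- gsub("{ref}", ref_fasta, aligner_cmd, fixed = TRUE)
    cmd <- gsub("{fastq}", fastq, cmd, fixed = TRUE)
    cmd <- gsub("{out}", out, cmd, fixed = TRUE)
    if (system(cmd) != 0L) stop("aligner command failed: ", cmd)
  }
  invisible(out)
}

#' Run one metagenome through the full pipeline
#'
#' parse -> filter -> depth -> GEQ -> cell fractions -> attribution ->
#' apportionment. Give either a SAM/BAM of alignments against the database
#' or a FASTQ (aligned via \code{\link{align_reads}}). When \code{out_dir}
#' is set, the attribution, apportionment, cell-fraction and per-genome
#' depth TSVs are written there together with the resolved configuration
#' and a stage-count log.
#'
#' @param db a \code{source_db}.
#' @param sam path to alignments (SAM/BAM), or NULL to align \code{fastq}.
#' @param fastq path to reads; required when \code{sam} is NULL.
#' @param config a \code{run_config}. A GEQ backend is required: either
#'   \code{ags_bp} or \code{marker_coords}.
#' @param sample_id sample label (default: SAM/FASTQ basename).
#' @param out_dir optional output directory.
#' @param ref_fasta optional pre-built reference FASTA for alignment.
#' @return a \code{\link{sample_report}}, with the \code{depth_table} and
#'   stage counts attached as attributes \code{depth} and \code{stages}.
#' @export
run_sample <- function(db, sam = NULL, fastq = NULL, config = run_config(),
                       sample_id = NULL, out_dir = NULL, ref_fasta = NULL) {
  stopifnot(inherits(db, "source_db"), inherits(config, "run_config"))
  if (is.null(sam)) {
    if (is.null(fastq)) stop("provide sam or fastq")
    sam <- file.path(tempdir(), paste0(basename(fastq), ".sam"))
    align_reads(fastq, db, out = sam, ref_fasta = ref_fasta,
                aligner_cmd = config$aligner_cmd)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(sam), ignore.case = TRUE)
  }
  if (is.null(config$ags_bp) && is.null(config$marker_coords)) {
    stop("config needs a GEQ backend: ags_bp or marker_coords")
  }

  aln <- parse_alignments(sam, db)
  filt <- filter_alignments(aln, min_identity = config$min_identity,
                            min_overlap = config$min_overlap)
  depth <- compute_depth(filt, db, masking_percent = config$masking_percent,
                         sample_id = sample_id)
  geq <- if (!is.null(config$ags_bp)) {
    estimate_geq(attr(aln, "total_bp"), ags_bp = config$ags_bp)
  } else {
    hits <- marker_hits_from_alignments(filt, config$marker_coords, db)
    estimate_geq(attr(aln, "total_bp"), marker_hits = hits)
  }
  fracs <- cell_fractions(depth, db, geq, min_reads = config$min_reads,
                          min_breadth = config$min_breadth)
  report <- sample_report(fracs, lod_percent = config$lod_percent)
  stages <- c(total_reads = attr(aln, "total_reads"),
              mapped_primary = nrow(aln), filtered = nrow(filt),
              filtered_aligned_bp = sum(filt$aligned_len))
  attr(report, "depth") <- depth
  attr(report, "stages") <- stages
  attr(report, "geq") <- geq

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sample_report(report, out_dir)
    write_depth_table(depth, file.path(out_dir, paste0(sample_id, "_depth.tsv")))
    write_run_config(config, file.path(out_dir, paste0(sample_id, "_config.txt")))
    writeLines(c(sprintf("sample=%s", sample_id),
                 sprintf("min_identity=%g min_overlap=%g masking_percent=%g lod_percent=%g",
                         config$min_identity, config$min_overlap,
                         config$masking_percent, config$lod_percent),
                 sprintf("geq=%.6g ags_bp=%.6g method=%s", geq$geq, geq$ags_bp, geq$method),
                 paste(names(stages), stages, sep = "=")),
               file.path(out_dir, paste0(sample_id, "_log.txt")))
  }
  report
}
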