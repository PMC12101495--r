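# Read-to-database alignment parsing and metric filtering.
#
# Alignments arrive as SAM produced by an external short-read aligner (bwa
# mem or compatible) or by the bundled simulator. Only primary mapped
# records are kept — multi-mapping across genomes is resolved by the
# aligner's primary flag, not re-assigned here. Per record we derive:
#   identity_percent = 100 * (aligned_len - NM) / aligned_len
#   overlap_fraction = aligned_len / read_len
# where aligned_len counts CIGAR query-consuming match operations (M, =, X)
# and read_len the full query length including clipped bases. Identity is NM
# over aligned query bases (bwa/CoverM-style accounting, not gap-compressed).

SAM_FLAG_UNMAPPED <- 0x4L
SAM_FLAG_SECONDARY <- 0x100L
SAM_FLAG_SUPPLEMENTARY <- 0x800L

# sum of CIGAR op lengths for the given ops, per record
cigar_op_sum <- function(cigar, ops) {
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar, ops = ops)
  vapply(lens, sum, integer(1))
}

#' Parse read-to-database alignments from SAM/BAM
#'
#' Keeps primary mapped records only (unmapped, secondary, and supplementary
#' records are dropped), maps reference contigs to genomes, and computes the
#' identity and overlap metrics used by \code{\link{filter_alignments}}.
#' Records without an NM (edit distance) tag are skipped with a counted
#' warning; a reference contig absent from the contig table is a hard error.
#'
#' @param sam path to a SAM or BAM file with NM tags.
#' @param db a \code{source_db} (its contig table maps contigs to genomes),
#'   or a data.frame with columns \code{contig}, \code{genome_id}.
#' @return data.frame with one row per retained alignment: \code{read_id},
#'   \code{genome_id}, \code{contig}, \code{pos} (1-based leftmost reference
#'   position), \code{read_len}, \code{aligned_len}, \code{ref_len},
#'   \code{edit_distance}, \code{identity_percent}, \code{overlap_fraction}.
#'   Attributes: \code{total_reads} and \code{total_bp} (all primary records
#'   including unmapped — the metagenome totals used for genome-equivalents
#'   normalization), \code{n_missing_nm}.
#' @export
parse_alignments <- function(sam, db) {
  contig_map <- if (inherits(db, "source_db")) db$contigs else
    as_tsv_table(db, c("contig", "genome_id"))
  bam <- sam
  if (!grepl("\\.bam$", sam, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM"))[[1L]]

  flag <- rec$flag
  primary <- bitwAnd(flag, SAM_FLAG_SECONDARY) == 0L &
    bitwAnd(flag, SAM_FLAG_SUPPLEMENTARY) == 0L
  qlen_all <- Biostrings::width(rec$seq)
  total_reads <- sum(primary)
  total_bp <- sum(qlen_all[primary])

  mapped <- primary & bitwAnd(flag, SAM_FLAG_UNMAPPED) == 0L
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  missing_nm <- mapped & is.na(nm)
  n_missing_nm <- sum(missing_nm)
  if (n_missing_nm > 0L) {
    warning(n_missing_nm, " mapped record(s) without NM tag skipped")
  }
  keep <- mapped & !is.na(nm)

  cigar <- rec$cigar[keep]
  contig <- as.character(rec$rname[keep])
  gi <- match(contig, contig_map$contig)
  if (anyNA(gi)) {
    stop("reference contig(s) not in the database contig table: ",
         paste(unique(contig[is.na(gi)]), collapse = ", "))
  }
  aligned_len <- cigar_op_sum(cigar, c("M", "=", "X"))
  ref_len <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  # full query length including soft clips; hard-clipped bases are absent
  # from SEQ, so add them back from the CIGAR
  read_len <- qlen_all[keep] + cigar_op_sum(cigar, "H")
  edit <- as.integer(nm[keep])

  out <- data.frame(
    read_id = rec$qname[keep],
    genome_id = contig_map$genome_id[gi],
    contig = contig,
    pos = rec$pos[keep],
    read_len = read_len,
    aligned_len = aligned_len,
    ref_len = ref_len,
    edit_distance = edit,
    identity_percent = 100 * (aligned_len - edit) / aligned_len,
    overlap_fraction = aligned_len / read_len,
    stringsAsFactors = FALSE)
  attr(out, "total_reads") <- total_reads
  attr(out, "total_bp") <- total_bp
  attr(out, "n_missing_nm") <- n_missing_nm
  out
}

#' Filter alignments on identity and overlap
#'
#' Retains exactly the records with \code{identity_percent >= min_identity}
#' and \code{100 * overlap_fraction >= min_overlap} (both thresholds
#' inclusive), preserving input order. The tuned defaults are 93% minimum
#' identity and 70% minimum alignment-to-read overlap.
#'
#' @param alignments data.frame from \code{\link{parse_alignments}}.
#' @param min_identity minimum alignment identity in percent (default 93).
#' @param min_overlap minimum alignment-to-read overlap in percent
#'   (default 70).
#' @return the retained subset, with the input's metagenome-total attributes
#'   carried over.
#' @export
filter_alignments <- function(alignments, min_identity = 93, min_overlap = 70) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_overlap > 0, min_overlap <= 100)
  keep <- alignments$identity_percent >= min_identity &
    100 * alignments$overlap_fraction >= min_overlap
  out <- alignments[keep, , drop = FALSE]
  for (a in c("total_reads", "total_bp", "n_missing_nm")) {
    attr(out, a) <- attr(alignments, a)
  }
  out
}
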