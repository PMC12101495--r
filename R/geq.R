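# Genome-equivalents (GEQ) normalization and cell fractions.
#
# GEQ is the number of genome copies in a metagenome: total sequenced bases
# divided by the community's average genome size (AGS). The cell fraction of
# a source category is the summed sequencing depth of its detected genomes
# over GEQ:
#
#   cell_fraction_j = sum_i X_i / GEQ
#
# split into a source-specific component (unflagged genomes) and a
# cross-reactive component. Two GEQ backends are supported: a user-supplied
# AGS, or a marker-coverage estimator (median per-marker coverage of
# universal single-copy markers, each present once per genome, equals the
# total genome-copy count).

#' Estimate metagenome genome equivalents
#'
#' Exactly one of \code{ags_bp} or \code{marker_hits} must be given.
#' With \code{ags_bp}: \code{geq = total_bp / ags_bp}. With
#' \code{marker_hits}: per-marker \code{geq_j = aligned_bp_j / marker_len_j};
#' the estimate is the median over markers with hits, and the implied AGS is
#' \code{total_bp / geq}.
#'
#' @param total_bp total sequenced bases in the metagenome.
#' @param ags_bp average genome size in bp (supplied-AGS backend).
#' @param marker_hits data.frame with columns \code{marker_id},
#'   \code{marker_len_bp}, \code{aligned_bp} (marker-coverage backend); see
#'   \code{\link{marker_hits_from_alignments}}.
#' @return An object of class \code{geq_estimate}: list with \code{geq},
#'   \code{ags_bp}, \code{total_bp}, \code{method}.
#' @export
estimate_geq <- function(total_bp, ags_bp = NULL, marker_hits = NULL) {
  if (is.null(ags_bp) == is.null(marker_hits)) {
    stop("provide exactly one of ags_bp or marker_hits")
  }
  stopifnot(total_bp > 0)
  if (!is.null(ags_bp)) {
    if (ags_bp <= 0) stop("ags_bp must be positive")
    geq <- total_bp / ags_bp
    method <- "supplied_ags"
  } else {
    marker_hits <- as_tsv_table(marker_hits,
                                c("marker_id", "marker_len_bp", "aligned_bp"))
    stopifnot(all(marker_hits$marker_len_bp > 0),
              all(marker_hits$aligned_bp >= 0))
    per <- marker_hits$aligned_bp / marker_hits$marker_len_bp
    per <- per[marker_hits$aligned_bp > 0]
    if (length(per) == 0L) stop("GEQ undefined: no marker has hits")
    geq <- stats::median(per)
    ags_bp <- total_bp / geq
    method <- "marker_coverage"
  }
  structure(list(geq = geq, ags_bp = ags_bp, total_bp = total_bp,
                 method = method), class = "geq_estimate")
}

#' @export
print.geq_estimate <- function(x, ...) {
  cat(sprintf("geq_estimate: %.4g genome equivalents (AGS %.4g bp, %s)\n",
              x$geq, x$ags_bp, x$method))
  invisible(x)
}

#' Marker alignment totals from filtered alignments
#'
#' For each universal single-copy marker, sums the reference-span overlap of
#' every filtered alignment with the marker's embedded location in its
#' genome. Feeds the marker-coverage GEQ backend.
#'
#' @param filtered alignments from \code{\link{filter_alignments}}.
#' @param marker_coords data.frame (or TSV path) with columns
#'   \code{genome_id}, \code{marker_id}, \code{start}, \code{end} (1-based,
#'   inclusive, in genome-concatenated coordinates); the synthetic-data
#'   generator emits this table.
#' @param db a \code{source_db} (for contig offsets).
#' @return data.frame marker_id, marker_len_bp, aligned_bp.
#' @export
marker_hits_from_alignments <- function(filtered, marker_coords, db) {
  mc <- as_tsv_table(marker_coords, c("genome_id", "marker_id", "start", "end"))
  ci <- match(filtered$contig, db$contigs$contig)
  a_start <- db$contigs$offset[ci] + filtered$pos
  a_end <- a_start + filtered$ref_len - 1L
  marker_ids <- sort(unique(mc$marker_id))
  out <- data.frame(marker_id = marker_ids,
                    marker_len_bp = NA_integer_,
                    aligned_bp = 0,
                    stringsAsFactors = FALSE)
  for (k in seq_along(marker_ids)) {
    rows <- mc[mc$marker_id == marker_ids[k], , drop = FALSE]
    out$marker_len_bp[k] <- rows$end[1L] - rows$start[1L] + 1L
    tot <- 0
    for (r in seq_len(nrow(rows))) {
      same <- filtered$genome_id == rows$genome_id[r]
      if (!any(same)) next
      ov <- pmin(a_end[same], rows$end[r]) - pmax(a_start[same], rows$start[r]) + 1L
      tot <- tot + sum(pmax(ov, 0L))
    }
    out$aligned_bp[k] <- tot
  }
  out
}

#' Per-category cell fractions
#'
#' Applies the detection rule, sums depth over detected genomes per category,
#' and normalizes by GEQ. The fraction is decomposed exactly into a
#' source-specific and a cross-reactive component. Signal of an aggregated
#' category (e.g. human genomes reported under wastewater) is moved into its
#' target category's cross-reactive component before reporting — it can
#' never satisfy the target's specific-genome condition. The environmental
#' screen's fraction is computed and labelled with its role.
#'
#' @param depths a \code{depth_table}.
#' @param db a \code{source_db}.
#' @param geq a \code{geq_estimate} with \code{geq > 0}.
#' @param min_reads detection rule: a genome is detected iff its filtered
#'   read count is at least this (default 1) ...
#' @param min_breadth ... and its breadth is at least this fraction
#'   (default 0).
#' @return An object of class \code{cell_fraction_table}: a data.frame with
#'   one row per reported category (\code{sample_id}, \code{category},
#'   \code{role}, \code{cell_fraction}, \code{specific_fraction},
#'   \code{cross_reactive_fraction}, \code{n_genomes_detected},
#'   \code{n_specific_detected}), with the \code{geq_estimate} and detection
#'   rule as attributes. Aggregated categories do not get their own row.
#' @export
cell_fractions <- function(depths, db, geq, min_reads = 1, min_breadth = 0) {
  stopifnot(inherits(geq, "geq_estimate"), geq$geq > 0)
  e <- depths$entries
  g <- db$genomes[match(e$genome_id, db$genomes$genome_id), ]
  detected <- e$n_reads >= min_reads & e$breadth >= min_breadth
  contrib <- ifelse(detected, e$depth / geq$geq, 0)
  specific <- !g$is_cross_reactive

  cats <- db$categories
  rows <- lapply(seq_len(nrow(cats)), function(i) {
    in_cat <- g$category == cats$name[i]
    data.frame(
      sample_id = depths$sample_id,
      category = cats$name[i],
      role = cats$role[i],
      cell_fraction = sum(contrib[in_cat]),
      specific_fraction = sum(contrib[in_cat & specific]),
      cross_reactive_fraction = sum(contrib[in_cat & !specific]),
      n_genomes_detected = sum(detected[in_cat]),
      n_specific_detected = sum(detected[in_cat] & specific[in_cat]),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  # fold aggregated categories into their targets (as cross-reactive signal)
  agg <- which(tab$role == "aggregate_into")
  for (i in agg) {
    target <- cats$aggregate_target[match(tab$category[i], cats$name)]
    j <- which(tab$category == target)
    tab$cell_fraction[j] <- tab$cell_fraction[j] + tab$cell_fraction[i]
    tab$cross_reactive_fraction[j] <-
      tab$cross_reactive_fraction[j] + tab$cell_fraction[i]
    tab$n_genomes_detected[j] <-
      tab$n_genomes_detected[j] + tab$n_genomes_detected[i]
  }
  if (length(agg) > 0L) tab <- tab[-agg, , drop = FALSE]
  rownames(tab) <- NULL

  structure(tab, class = c("cell_fraction_table", "data.frame"),
            geq = geq, min_reads = min_reads, min_breadth = min_breadth)
}

#' Write a cell-fraction table as TSV
#'
#' @param x a \code{cell_fraction_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cell_fractions <- function(x, path) {
  geq <- attr(x, "geq")
  df <- as.data.frame(x)
  df$geq <- geq$geq
  df$ags_bp <- geq$ags_bp
  write_tsv(df, path,
            comment = sprintf("min_reads=%g min_breadth=%g geq_method=%s",
                              attr(x, "min_reads"), attr(x, "min_breadth"),
                              geq$method))
}
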