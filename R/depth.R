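# Per-genome sequencing depth, breadth, and read counts.
#
# Coverage is accumulated per genome over the concatenation of its contigs
# using a difference array (+1 at alignment start, -1 past its end), so the
# per-base coverage vector is exact and linear-time. "Masking" removes the
# extreme coverage positions before averaging (trimmed-mean semantics): with
# masking_percent = m, the m/2 % highest- and m/2 % lowest-coverage positions
# of each genome are excluded; m = 0 is the plain mean and is the tuned
# default. Breadth is the fraction of retained positions covered at least
# once.

#' Compute per-genome depth, breadth, and read counts
#'
#' @param filtered data.frame of alignments from
#'   \code{\link{filter_alignments}} (needs \code{genome_id}, \code{contig},
#'   \code{pos}, \code{ref_len}, \code{aligned_len}).
#' @param db a \code{source_db}; every genome in the database gets an entry,
#'   zero-filled when nothing mapped to it.
#' @param masking_percent total percentage of extreme-coverage positions to
#'   exclude before averaging, in [0, 100); default 0 (plain mean).
#' @param sample_id label carried into the table.
#' @param total_reads,total_bp metagenome totals; default taken from the
#'   attributes \code{\link{parse_alignments}} attaches.
#' @return An object of class \code{depth_table}: list with \code{sample_id},
#'   \code{entries} (data.frame genome_id, category, depth, breadth, n_reads,
#'   aligned_bp), \code{total_reads}, \code{total_bp},
#'   \code{masking_percent}, \code{n_clipped} (alignments overhanging a
#'   contig end, clipped with a warning).
#' @export
compute_depth <- function(filtered, db, masking_percent = 0,
                          sample_id = "sample",
                          total_reads = attr(filtered, "total_reads"),
                          total_bp = attr(filtered, "total_bp")) {
  stopifnot(masking_percent >= 0, masking_percent < 100)
  g <- db$genomes
  cmap <- db$contigs
  ci <- match(filtered$contig, cmap$contig)
  if (anyNA(ci)) stop("alignment references unknown contig")

  # genome-concatenated half-open intervals [start, end)
  start <- cmap$offset[ci] + filtered$pos
  end_excl <- start + filtered$ref_len
  contig_end <- cmap$offset[ci] + cmap$length[ci]
  over <- end_excl > contig_end + 1L
  n_clipped <- sum(over)
  if (n_clipped > 0L) {
    warning(n_clipped, " alignment(s) overhanging a contig end were clipped")
    end_excl[over] <- contig_end[over] + 1L
  }

  depth <- breadth <- numeric(nrow(g))
  n_reads <- aligned_bp <- integer(nrow(g))
  idx_by_genome <- split(seq_len(nrow(filtered)), filtered$genome_id)
  for (k in seq_len(nrow(g))) {
    gid <- g$genome_id[k]
    idx <- idx_by_genome[[gid]]
    if (is.null(idx)) next
    L <- g$length_bp[k]
    d <- integer(L + 1L)
    s <- start[idx]
    e <- end_excl[idx]
    ds <- tapply(rep(1L, length(s)), s, sum)
    d[as.integer(names(ds))] <- as.integer(ds)
    de <- tapply(rep(1L, length(e)), e, sum)
    at <- as.integer(names(de))
    d[at] <- d[at] - as.integer(de)
    cov <- cumsum(d[seq_len(L)])
    n_trim <- floor(L * masking_percent / 200)
    if (n_trim > 0L) {
      cov <- sort(cov)[(n_trim + 1L):(L - n_trim)]
    }
    depth[k] <- mean(cov)
    breadth[k] <- mean(cov > 0L)
    n_reads[k] <- length(idx)
    aligned_bp[k] <- sum(filtered$aligned_len[idx])
  }

  structure(list(
    sample_id = sample_id,
    entries = data.frame(genome_id = g$genome_id, category = g$category,
                         depth = depth, breadth = breadth, n_reads = n_reads,
                         aligned_bp = aligned_bp, stringsAsFactors = FALSE),
    total_reads = if (is.null(total_reads)) NA_integer_ else total_reads,
    total_bp = if (is.null(total_bp)) NA_real_ else total_bp,
    masking_percent = masking_percent,
    n_clipped = n_clipped
  ), class = "depth_table")
}

#' @export
print.depth_table <- function(x, ...) {
  det <- x$entries[x$entries$n_reads > 0L, ]
  cat(sprintf("depth_table '%s': %d/%d genomes with signal, masking %g%%\n",
              x$sample_id, nrow(det), nrow(x$entries), x$masking_percent))
  if (nrow(det) > 0L) {
    print(utils::head(det[order(-det$depth), ], 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Write a depth table as TSV
#'
#' Columns: genome_id, category, depth, breadth, n_reads, aligned_bp.
#'
#' @param x a \code{depth_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_depth_table <- function(x, path) {
  write_tsv(x$entries, path,
            comment = sprintf("sample=%s masking_percent=%g total_reads=%s total_bp=%s",
                              x$sample_id, x$masking_percent,
                              x$total_reads, x$total_bp))
}
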