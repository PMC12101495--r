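# Source attribution (presence calls) and apportionment.
#
# A fecal-source category is called present only when two conditions hold:
#   1. at least one of its source-specific (unflagged) genomes is detected;
#   2. its estimated cell fraction strictly exceeds the limit of detection
#      (LOD, percent relative abundance; default 0.01%).
# Signal carried entirely by cross-reactive genomes is disregarded, and the
# environmental screen is always excluded. Apportionment then divides each
# present source's full cell fraction (specific + cross-reactive) by the sum
# over all present sources:
#
#   portion_j = cell_fraction_j / sum_{i present} cell_fraction_i
#
# which makes portions invariant to any uniform rescaling of the fractions
# (GEQ error cancels).

#' Presence calls per source category
#'
#' @param fractions a \code{cell_fraction_table} (aggregation rules already
#'   applied by \code{\link{cell_fractions}}).
#' @param lod_percent limit of detection, in percent relative abundance;
#'   the category's cell fraction must strictly exceed it (default 0.01).
#' @return An object of class \code{source_calls}: a data.frame with one row
#'   per reported category: \code{sample_id}, \code{category},
#'   \code{present}, \code{reason} (one of specific_and_above_lod,
#'   below_lod, no_specific_genome, screen_excluded), \code{cell_fraction},
#'   \code{n_specific_detected}; \code{lod_percent} is an attribute.
#' @export
attribute_sources <- function(fractions, lod_percent = 0.01) {
  f <- as.data.frame(fractions)
  screen <- f$role == "environmental_screen"
  has_specific <- f$n_specific_detected >= 1L
  above_lod <- f$cell_fraction * 100 > lod_percent
  present <- !screen & has_specific & above_lod
  reason <- ifelse(screen, "screen_excluded",
            ifelse(present, "specific_and_above_lod",
            ifelse(!has_specific, "no_specific_genome", "below_lod")))
  out <- data.frame(sample_id = f$sample_id, category = f$category,
                    present = present, reason = reason,
                    cell_fraction = f$cell_fraction,
                    n_specific_detected = f$n_specific_detected,
                    stringsAsFactors = FALSE)
  structure(out, class = c("source_calls", "data.frame"),
            lod_percent = lod_percent)
}

#' Apportion fecal signal among present sources
#'
#' @param fractions the \code{cell_fraction_table} the calls were derived
#'   from.
#' @param calls a \code{source_calls} table.
#' @return named numeric vector of portions over present fecal categories
#'   (sums to 1); empty when no source is present.
#' @export
apportion_sources <- function(fractions, calls) {
  f <- as.data.frame(fractions)
  pres <- calls$category[calls$present]
  if (length(pres) == 0L) return(stats::setNames(numeric(0), character(0)))
  cf <- f$cell_fraction[match(pres, f$category)]
  stats::setNames(cf / sum(cf), pres)
}

#' Bundle calls, fractions, and portions into a sample report
#'
#' @param fractions a \code{cell_fraction_table}.
#' @param lod_percent limit of detection in percent (default 0.01).
#' @return An object of class \code{sample_report}: list with
#'   \code{sample_id}, \code{calls}, \code{fractions}, \code{portions},
#'   \code{lod_percent}.
#' @export
sample_report <- function(fractions, lod_percent = 0.01) {
  calls <- attribute_sources(fractions, lod_percent)
  structure(list(sample_id = fractions$sample_id[1L],
                 calls = calls,
                 fractions = fractions,
                 portions = apportion_sources(fractions, calls),
                 lod_percent = lod_percent),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("sample_report '%s' (LOD %g%%)\n", x$sample_id, x$lod_percent))
  f <- x$calls
  f$portion <- ifelse(f$category %in% names(x$portions),
                      signif(x$portions[f$category], 4), NA)
  f$cell_fraction <- signif(f$cell_fraction, 4)
  print(f, row.names = FALSE)
  invisible(x)
}

#' Write a sample report as TSV files
#'
#' Writes \code{<sample>_attribution.tsv} (sample, category, present,
#' reason, cell_fraction, n_specific) and \code{<sample>_apportionment.tsv}
#' (sample, category, portion). A sample with no present source still gets
#' an explicit all-absent attribution file and an empty (header-only)
#' apportionment file.
#'
#' @param report a \code{sample_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_sample_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- report$sample_id
  write_tsv(as.data.frame(report$calls),
            file.path(dir, paste0(s, "_attribution.tsv")),
            comment = sprintf("lod_percent=%g", report$lod_percent))
  app <- data.frame(sample_id = rep(s, length(report$portions)),
                    category = names(report$portions),
                    portion = unname(report$portions),
                    stringsAsFactors = FALSE)
  write_tsv(app, file.path(dir, paste0(s, "_apportionment.tsv")))
  write_cell_fractions(report$fractions,
                       file.path(dir, paste0(s, "_cell_fractions.tsv")))
  invisible(dir)
}
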