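# Fragment-based average nucleotide identity (ANI) estimation.
#
# Cross-reactivity flagging only needs to discriminate around the ~95%
# species boundary, so the estimator is deliberately coarse: the query is cut
# into non-overlapping fragments, each fragment is seeded onto the reference
# by shared k-mers and scored by ungapped comparison, and ANI is the mean
# identity of fragments that place above a floor identity. No indel alignment
# is attempted; placement ties resolve to the leftmost reference position and
# both strands are tried per fragment.

# Build a k-mer position index of a sequence as a hashed environment
# kmer -> integer vector of 1-based start positions.
kmer_index <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(new.env(parent = emptyenv()))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  list2env(split(starts, kmers), envir = new.env(parent = emptyenv()))
}

# Place one fragment on the reference by voting over seed k-mer offsets,
# then score an ungapped comparison at the winning diagonal.
# Returns identity in percent of the full fragment length (overhangs count
# as mismatches), or NA when no seed k-mer is shared.
place_fragment <- function(frag, ref, idx, k) {
  flen <- nchar(frag)
  seed_pos <- unique(c(seq(1L, max(1L, flen - k + 1L), by = max(1L, k)),
                       max(1L, flen - k + 1L)))
  seeds <- substring(frag, seed_pos, seed_pos + k - 1L)
  offs <- integer(0)
  for (i in seq_along(seeds)) {
    hits <- idx[[seeds[i]]]
    if (!is.null(hits)) offs <- c(offs, hits - seed_pos[i] + 1L)
  }
  if (length(offs) == 0L) return(NA_real_)
  tab <- table(offs)
  best <- as.integer(names(tab)[tab == max(tab)])
  off <- min(best)  # leftmost reference position on ties
  rlen <- nchar(ref)
  q_from <- max(1L, 2L - off)              # clip fragment to reference bounds
  q_to <- min(flen, rlen - off + 1L)
  if (q_to < q_from) return(NA_real_)
  a <- utf8ToInt(substring(frag, q_from, q_to))
  b <- utf8ToInt(substring(ref, off + q_from - 1L, off + q_to - 1L))
  100 * sum(a == b) / flen
}

#' Estimate average nucleotide identity between two sequences
#'
#' Fragment-based ANI: the query is cut into non-overlapping fragments of
#' \code{fragment_len} bp, each fragment is placed on the reference via
#' shared \code{kmer_len}-mers (both strands; best strand wins) and scored by
#' ungapped comparison. Fragments whose identity falls below
#' \code{min_fragment_identity} are discarded; ANI is the mean identity of
#' the retained fragments.
#'
#' @param query_seq,ref_seq nucleotide sequences as character strings (or
#'   anything \code{as.character} turns into one).
#' @param fragment_len fragment size in bp (default 1000).
#' @param kmer_len seed k-mer length (default 15).
#' @param min_fragment_identity per-fragment identity floor in percent
#'   (default 80); fragments below it do not contribute to ANI.
#' @param query_id,reference_id labels carried into the result.
#' @return An object of class \code{ani_result}: a list with
#'   \code{ani_percent} (NA when no fragment places), \code{aligned_fraction}
#'   (retained fragments / total fragments), \code{n_fragments_used} and
#'   \code{n_fragments_total}.
#' @export
estimate_ani <- function(query_seq, ref_seq, fragment_len = 1000L,
                         kmer_len = 15L, min_fragment_identity = 80,
                         query_id = "query", reference_id = "reference") {
  query_seq <- toupper(as.character(query_seq))
  ref_seq <- toupper(as.character(ref_seq))
  if (nchar(query_seq) == 0L || nchar(ref_seq) == 0L) {
    stop("both sequences must be non-empty")
  }
  if (fragment_len < kmer_len) stop("fragment_len must be >= kmer_len")

  qlen <- nchar(query_seq)
  if (qlen < fragment_len) {
    warning("query shorter than fragment_len; using a single truncated fragment")
    frags <- query_seq
  } else {
    n_frag <- qlen %/% fragment_len
    starts <- (seq_len(n_frag) - 1L) * fragment_len + 1L
    frags <- substring(query_seq, starts, starts + fragment_len - 1L)
  }

  idx <- kmer_index(ref_seq, kmer_len)
  ids <- vapply(frags, function(f) {
    both <- c(place_fragment(f, ref_seq, idx, kmer_len),
              place_fragment(revcomp(f), ref_seq, idx, kmer_len))
    both <- both[!is.na(both)]
    if (length(both) == 0L) NA_real_ else max(both)
  }, numeric(1), USE.NAMES = FALSE)

  kept <- ids[!is.na(ids) & ids >= min_fragment_identity]
  structure(list(
    query_id = query_id,
    reference_id = reference_id,
    ani_percent = if (length(kept) > 0L) mean(kept) else NA_real_,
    aligned_fraction = length(kept) / length(frags),
    n_fragments_used = length(kept),
    n_fragments_total = length(frags)
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %s (%d/%d fragments)\n",
              x$query_id, x$reference_id,
              if (is.na(x$ani_percent)) "undefined"
              else sprintf("%.2f%%", x$ani_percent),
              x$n_fragments_used, x$n_fragments_total))
  invisible(x)
}

#' All-vs-all ANI over a genome manifest
#'
#' Runs \code{\link{estimate_ani}} for every ordered pair of distinct
#' genomes in a manifest and returns the table consumed by
#' \code{\link{build_source_db}}.
#'
#' @param manifest data.frame with columns \code{genome_id}, \code{path},
#'   \code{category}, or a path to the headerless manifest TSV.
#' @param ... passed to \code{\link{estimate_ani}}.
#' @param out optional path; when given the table is also written as a TSV
#'   (query, reference, ani_percent).
#' @return data.frame with columns \code{query}, \code{reference},
#'   \code{ani_percent} (rows with undefined ANI are omitted).
#' @export
ani_all_pairs <- function(manifest, ..., out = NULL) {
  manifest <- as_tsv_table(manifest, c("genome_id", "path", "category"))
  seqs <- vapply(manifest$path, function(p) {
    paste(as.character(Biostrings::readDNAStringSet(p)), collapse = "")
  }, "", USE.NAMES = FALSE)
  n <- nrow(manifest)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- estimate_ani(seqs[i], seqs[j], ...,
                        query_id = manifest$genome_id[i],
                        reference_id = manifest$genome_id[j])
      if (!is.na(r$ani_percent)) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = r$query_id, reference = r$reference_id,
          ani_percent = r$ani_percent, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(query = character(0), reference = character(0),
               ani_percent = numeric(0))
  if (!is.null(out)) write_tsv(res, out)
  res
}
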