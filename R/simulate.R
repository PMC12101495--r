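# Synthetic spike-in benchmark generator.
#
# Emulates the construction of ground-truth mesocosms: a background water
# community spiked with fecal-source communities at known cell fractions.
# Genomes are uniform-random toy sequences, one per species, each carrying
# every universal single-copy marker exactly once (so marker-coverage GEQ
# estimation has a handle). Cross-reactivity is engineered by cloning a
# genome into two categories with i.i.d. substitutions at a chosen
# divergence. Reads are substitution-only (no indels), so the truth SAM has
# all-M CIGARs and the edit distance is analytically known. All randomness
# flows from one explicit seed, which is recorded in every output header.

#' Generate toy genomes, manifest, and markers
#'
#' One single-contig genome per species, uniform-random sequence, with
#' \code{n_markers} universal single-copy marker sequences embedded exactly
#' once per genome at evenly spaced anchor blocks. Shared species are
#' engineered by cloning a genome of one category over a genome slot of a
#' second category with i.i.d. substitutions at the stated divergence
#' (divergence d gives an expected ANI of about 100(1-d); keep d at or
#' below 0.05 for the pair to flag at the 95% threshold).
#'
#' @param n_per_category named integer vector: genomes per category.
#' @param genome_len genome length in bp (default 20000; all genomes equal
#'   length, so read fractions equal cell fractions exactly).
#' @param shared_species optional data.frame with columns
#'   \code{category_a}, \code{category_b}, \code{divergence}: each row
#'   clones the next unused genome of category_a over the next unused
#'   genome slot of category_b.
#' @param n_markers number of universal markers (default 3).
#' @param marker_len marker length in bp (default 400).
#' @param seed integer seed; recorded in the manifest header.
#' @param dir output directory for the FASTA files and tables.
#' @return list with \code{manifest} (genome_id, path, category),
#'   \code{marker_coords} (genome_id, marker_id, start, end),
#'   \code{marker_fasta}, \code{dir}, \code{seed}. The manifest and marker
#'   coordinates are also written as TSVs in \code{dir}.
#' @export
generate_genomes <- function(n_per_category, genome_len = 20000L,
                             shared_species = NULL, n_markers = 3L,
                             marker_len = 400L, seed = 1L,
                             dir = tempfile("genomes")) {
  stopifnot(length(n_per_category) > 0, !is.null(names(n_per_category)),
            all(n_per_category >= 1), n_markers >= 0)
  if (n_markers > 0L && genome_len < 2L * n_markers * marker_len) {
    stop("genome_len too small for ", n_markers, " markers of ", marker_len, " bp")
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  markers <- vapply(seq_len(n_markers), function(i) random_dna(marker_len), "")
  marker_ids <- sprintf("marker%02d", seq_len(n_markers))

  cats <- names(n_per_category)
  manifest <- data.frame(genome_id = character(0), path = character(0),
                         category = character(0), stringsAsFactors = FALSE)
  seqs <- list()
  coords <- list()
  block <- genome_len %/% n_markers  # one marker per block, random offset
  for (cat_name in cats) {
    for (k in seq_len(n_per_category[[cat_name]])) {
      gid <- sprintf("%s_g%02d", cat_name, k)
      s <- random_dna(genome_len)
      starts <- integer(n_markers)
      for (mi in seq_len(n_markers)) {
        lo <- (mi - 1L) * block + 1L
        hi <- mi * block - marker_len
        st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        substr(s, st, st + marker_len - 1L) <- markers[mi]
        starts[mi] <- st
      }
      seqs[[gid]] <- s
      coords[[gid]] <- data.frame(genome_id = rep(gid, n_markers),
                                  marker_id = marker_ids,
                                  start = starts, end = starts + marker_len - 1L,
                                  stringsAsFactors = FALSE)
      manifest <- rbind(manifest, data.frame(
        genome_id = gid, path = file.path(dir, paste0(gid, ".fasta")),
        category = cat_name, stringsAsFactors = FALSE))
    }
  }

  if (!is.null(shared_species)) {
    shared_species <- as_tsv_table(shared_species,
                                   c("category_a", "category_b", "divergence"))
    used_a <- used_b <- stats::setNames(integer(length(cats)), cats)
    for (r in seq_len(nrow(shared_species))) {
      ca <- shared_species$category_a[r]
      cb <- shared_species$category_b[r]
      d <- shared_species$divergence[r]
      stopifnot(ca %in% cats, cb %in% cats, d >= 0, d <= 0.25)
      used_a[ca] <- used_a[ca] + 1L
      used_b[cb] <- used_b[cb] + 1L
      ga <- sprintf("%s_g%02d", ca, used_a[ca])
      gb <- sprintf("%s_g%02d", cb, n_per_category[[cb]] - used_b[cb] + 1L)
      mut <- mutate_seqs(seqs[[ga]], d)
      seqs[[gb]] <- mut$seq
      coords[[gb]][, c("start", "end")] <- coords[[ga]][, c("start", "end")]
    }
  }

  for (gid in manifest$genome_id) {
    writeLines(c(paste0(">", gid), seqs[[gid]]), manifest$path[manifest$genome_id == gid])
  }
  marker_fasta <- file.path(dir, "markers.fasta")
  writeLines(as.vector(rbind(paste0(">", marker_ids), markers)), marker_fasta)

  marker_coords <- do.call(rbind, coords)
  rownames(marker_coords) <- NULL
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(marker_coords, file.path(dir, "marker_coords.tsv"),
            comment = sprintf("seed=%d", seed))
  list(manifest = manifest, marker_coords = marker_coords,
       marker_fasta = marker_fasta, dir = dir, seed = seed)
}

#' True cell fractions of a mixture design
#'
#' The mixture model of mesocosm construction: each source i contributes
#' rho_i * V_i cells (density times spiked volume) into a background of
#' rho_bg * V_bg cells, and
#'
#'   fraction_i = rho_i V_i / (sum_j rho_j V_j + rho_bg V_bg)
#'
#' computed exactly.
#'
#' @param rho named numeric vector of source cell densities (cells/mL).
#' @param volume named numeric vector of spiked volumes (mL), same names.
#' @param rho_background,volume_background background water density and
#'   volume.
#' @return named numeric vector of source cell fractions, with the
#'   background fraction as attribute \code{background}.
#' @export
true_cell_fractions <- function(rho, volume, rho_background, volume_background) {
  stopifnot(length(rho) == length(volume),
            identical(names(rho), names(volume)),
            all(rho >= 0), all(volume >= 0),
            rho_background >= 0, volume_background >= 0)
  cells <- rho * volume
  total <- sum(cells) + rho_background * volume_background
  if (total <= 0) stop("mixture contains no cells")
  structure(cells / total, background = rho_background * volume_background / total)
}

# write a FASTQ with constant Phred-33 quality
write_fastq <- function(ids, seqs, path, qual_char = "I") {
  n <- length(ids)
  qual <- strrep(qual_char, nchar(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, rep("+", n), qual)), con)
  invisible(path)
}

#' Simulate a spike-in metagenome with exact ground truth
#'
#' Draws each read's origin category proportional to its cell fraction
#' (remainder goes to the background category), origin genome uniform
#' within the category (equal genome copies; set \code{skew} for a
#' geometric rank-abundance series), position and strand uniform, and
#' applies i.i.d. substitutions at \code{error_rate}. Alongside the FASTQ a
#' truth SAM is written with the exact origin coordinates, all-M CIGARs and
#' NM tags, so the pipeline can run without an external aligner; a per-read
#' provenance table and the ground-truth cell-fraction table are emitted
#' too.
#'
#' @param genomes result of \code{\link{generate_genomes}}, or a manifest
#'   data.frame with columns genome_id, path, category.
#' @param fractions named numeric vector of cell fractions per source
#'   category (needs not cover all categories; must sum to at most 1).
#' @param background_category category receiving the remaining fraction
#'   (default \code{"environmental"}; use NA for no background reads).
#' @param n_reads number of reads (> 0).
#' @param read_len read length in bp (default 150).
#' @param error_rate per-base substitution rate in [0, 0.25] (default 0).
#' @param skew optional geometric rank-abundance ratio in (0, 1]; genome k
#'   of a category gets weight skew^(k-1). Default NULL = equal copies.
#' @param seed integer seed; recorded in all output headers.
#' @param dir output directory.
#' @param sample_id sample label (default "sim").
#' @return An object of class \code{sim_sample}: list with \code{sample_id},
#'   \code{fastq}, \code{sam}, \code{provenance} (path),
#'   \code{ground_truth} (data.frame sample_id, category,
#'   true_cell_fraction over all non-background categories, also written as
#'   TSV), \code{fractions}, \code{background_fraction}, \code{n_reads},
#'   \code{read_len}, \code{error_rate}, \code{seed}.
#' @export
simulate_reads <- function(genomes, fractions, background_category = "environmental",
                           n_reads, read_len = 150L, error_rate = 0,
                           skew = NULL, seed = 1L, dir = tempfile("sim"),
                           sample_id = "sim") {
  manifest <- if (is.data.frame(genomes)) genomes else genomes$manifest
  manifest <- as_tsv_table(manifest, c("genome_id", "path", "category"))
  stopifnot(n_reads > 0, error_rate >= 0, error_rate <= 0.25,
            all(fractions >= 0), sum(fractions) <= 1 + 1e-12)
  bg <- 1 - sum(fractions)
  cats <- names(fractions)
  if (!all(cats %in% manifest$category)) {
    stop("fraction categories missing from the manifest: ",
         paste(setdiff(cats, manifest$category), collapse = ", "))
  }
  if (bg > 1e-12) {
    if (is.na(background_category)) stop("fractions sum to < 1 but no background category")
    if (!background_category %in% manifest$category) {
      stop("background category missing from the manifest: ", background_category)
    }
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  seqs <- vapply(manifest$path, function(p) {
    paste(as.character(Biostrings::readDNAStringSet(p)), collapse = "")
  }, "", USE.NAMES = FALSE)
  glen <- nchar(seqs)
  if (any(glen < read_len)) stop("read_len exceeds a genome length")

  # per-genome sampling weight: category fraction x within-category copies
  w <- numeric(nrow(manifest))
  weight_cat <- function(cat_name, frac) {
    idx <- which(manifest$category == cat_name)
    copies <- if (is.null(skew)) rep(1, length(idx)) else skew^(seq_along(idx) - 1)
    w[idx] <<- frac * copies / sum(copies)
  }
  for (cat_name in cats) weight_cat(cat_name, fractions[[cat_name]])
  if (bg > 1e-12) {
    weight_cat(background_category,
               bg + if (background_category %in% cats) fractions[[background_category]] else 0)
  }
  if (sum(w) <= 0) stop("no genome has positive sampling weight")

  gidx <- sample.int(nrow(manifest), n_reads, replace = TRUE, prob = w)
  pos <- 1L + floor(stats::runif(n_reads) * (glen[gidx] - read_len + 1L))
  strand <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)  # TRUE = reverse
  ref_seq <- substring(seqs[gidx], pos, pos + read_len - 1L)
  mut <- if (error_rate > 0) mutate_reads(ref_seq, read_len, error_rate)
         else list(seq = ref_seq, n_sub = integer(n_reads))
  # FASTQ carries the sequenced orientation; SAM carries reference orientation
  fastq_seq <- mut$seq
  fastq_seq[strand] <- revcomp(fastq_seq[strand])
  ids <- sprintf("%s_r%07d", sample_id, seq_len(n_reads))

  fastq <- file.path(dir, paste0(sample_id, ".fastq"))
  write_fastq(ids, fastq_seq, fastq)

  sam <- file.path(dir, paste0(sample_id, ".sam"))
  gorder <- order(manifest$genome_id)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", manifest$genome_id[gorder], glen[gorder]),
              sprintf("@CO\tfstrack simulator seed=%d error_rate=%g n_reads=%d",
                      seed, error_rate, n_reads))
  recs <- paste(ids, ifelse(strand, 16L, 0L), manifest$genome_id[gidx], pos,
                60L, paste0(read_len, "M"), "*", 0L, 0L, mut$seq,
                strrep("I", read_len), paste0("NM:i:", mut$n_sub), sep = "\t")
  writeLines(c(header, recs), sam)

  provenance <- file.path(dir, paste0(sample_id, "_provenance.tsv"))
  write_tsv(data.frame(read_id = ids, category = manifest$category[gidx],
                       genome_id = manifest$genome_id[gidx], start = pos,
                       strand = ifelse(strand, "-", "+"),
                       n_errors = mut$n_sub, stringsAsFactors = FALSE),
            provenance, comment = sprintf("seed=%d", seed))

  truth_cats <- setdiff(unique(manifest$category),
                        if (is.na(background_category)) character(0) else background_category)
  gt <- data.frame(sample_id = sample_id, category = truth_cats,
                   true_cell_fraction = ifelse(truth_cats %in% cats,
                                               unname(fractions[truth_cats]), 0),
                   stringsAsFactors = FALSE)
  gt$true_cell_fraction[is.na(gt$true_cell_fraction)] <- 0
  write_tsv(gt, file.path(dir, paste0(sample_id, "_ground_truth.tsv")),
            comment = sprintf("seed=%d", seed))

  structure(list(sample_id = sample_id, fastq = fastq, sam = sam,
                 provenance = provenance, ground_truth = gt,
                 fractions = fractions, background_fraction = bg,
                 n_reads = n_reads, read_len = read_len,
                 error_rate = error_rate, seed = seed, dir = dir),
            class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("sim_sample '%s': %d reads x %d bp, error rate %g, seed %d\n",
              x$sample_id, x$n_reads, x$read_len, x$error_rate, x$seed))
  cat("  spiked:", if (length(x$fractions) > 0)
    paste(sprintf("%s=%.3g", names(x$fractions), x$fractions), collapse = ", ")
    else "none", sprintf(" background=%.3g\n", x$background_fraction))
  invisible(x)
}
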