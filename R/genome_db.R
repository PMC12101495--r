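# Source-labelled genome database with cross-reactivity flagging.
#
# A database is a set of genomes, each assigned to one source category
# (wastewater, cow, dog, ..., or user-defined). Genome pairs sitting in
# *different* categories whose ANI meets the species boundary (default 95%)
# are flagged cross-reactive on both sides: their mapped signal still counts
# toward a category's cell fraction, but cannot by itself establish that the
# category is present. One category may act as an environmental screen
# (autochthonous background genomes whose signal is excluded from
# apportionment), and a category may be aggregated into another (e.g.
# human-specific genomes reported inside wastewater).

#' Build a source-labelled genome database
#'
#' Reads the genome manifest, validates the FASTA files, applies
#' cross-reactivity flagging from an ANI table, and records the screen and
#' aggregation roles.
#'
#' Flagging rule: a pair of genomes in different source categories is flagged
#' cross-reactive (symmetrically, on both genomes) when the larger of the two
#' directed ANI values reported for the pair is greater than or equal to
#' \code{ani_threshold}. Pairs absent from the table are treated as below
#' threshold; same-category pairs are never flagged.
#'
#' @param manifest data.frame with columns \code{genome_id}, \code{path},
#'   \code{category}, or a path to a headerless TSV in that column order.
#'   Each path is a (multi-contig) nucleotide FASTA; one file = one genome.
#' @param ani ANI table: data.frame with columns \code{query},
#'   \code{reference}, \code{ani_percent}, a path to such a TSV, or NULL for
#'   no flagging. \code{\link{ani_all_pairs}} produces this format.
#' @param ani_threshold flagging threshold in percent (default 95).
#' @param screen_category optional category name to act as the environmental
#'   screen; at most one per database.
#' @param aggregation_rules optional named character vector mapping a
#'   category to the fecal-source category its signal is reported under,
#'   e.g. \code{c(human = "wastewater")}.
#' @return An object of class \code{source_db}: a list with \code{genomes}
#'   (one row per genome: id, category, path, length_bp, n_contigs,
#'   is_cross_reactive), \code{cross_reactive_with} (named list of partner
#'   genome ids), \code{contigs} (contig -> genome map with offsets),
#'   \code{categories} (name, role, aggregate_target) and
#'   \code{ani_threshold}.
#' @export
build_source_db <- function(manifest, ani = NULL, ani_threshold = 95,
                            screen_category = NULL, aggregation_rules = NULL) {
  manifest <- as_tsv_table(manifest, c("genome_id", "path", "category"))
  manifest$genome_id <- as.character(manifest$genome_id)
  manifest$category <- as.character(manifest$category)
  dup <- manifest$genome_id[duplicated(manifest$genome_id)]
  if (length(dup) > 0L) {
    stop("duplicate genome_id in manifest: ", paste(unique(dup), collapse = ", "))
  }

  contig_rows <- vector("list", nrow(manifest))
  length_bp <- integer(nrow(manifest))
  n_contigs <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) stop("FASTA not found: ", p)
    ss <- Biostrings::readDNAStringSet(p)
    if (length(ss) == 0L || sum(Biostrings::width(ss)) == 0L) {
      stop("empty FASTA: ", p)
    }
    w <- Biostrings::width(ss)
    contig_rows[[i]] <- data.frame(
      contig = sub("\\s.*$", "", names(ss)),
      genome_id = manifest$genome_id[i],
      length = w,
      offset = cumsum(c(0L, w[-length(w)])),
      stringsAsFactors = FALSE)
    length_bp[i] <- sum(w)
    n_contigs[i] <- length(ss)
  }
  contigs <- do.call(rbind, contig_rows)
  dupc <- contigs$contig[duplicated(contigs$contig)]
  if (length(dupc) > 0L) {
    stop("contig names must be unique across genomes: ",
         paste(unique(dupc), collapse = ", "))
  }

  cats <- unique(manifest$category)
  roles <- rep("fecal_source", length(cats))
  targets <- rep(NA_character_, length(cats))
  if (!is.null(screen_category)) {
    if (!screen_category %in% cats) stop("unknown screen category: ", screen_category)
    roles[cats == screen_category] <- "environmental_screen"
  }
  if (!is.null(aggregation_rules)) {
    for (from in names(aggregation_rules)) {
      to <- aggregation_rules[[from]]
      if (!from %in% cats) stop("unknown category in aggregation rule: ", from)
      if (!to %in% cats || roles[cats == to] != "fecal_source") {
        stop("aggregation target must be an existing fecal_source category: ", to)
      }
      if (roles[cats == from] != "fecal_source") {
        stop("cannot aggregate the screen category")
      }
      roles[cats == from] <- "aggregate_into"
      targets[cats == from] <- to
    }
  }
  categories <- data.frame(name = cats, role = roles,
                           aggregate_target = targets, stringsAsFactors = FALSE)

  cross <- stats::setNames(vector("list", nrow(manifest)), manifest$genome_id)
  cross[] <- list(character(0))
  if (!is.null(ani)) {
    ani <- as_tsv_table(ani, c("query", "reference", "ani_percent"))
    known <- manifest$genome_id
    cat_of <- stats::setNames(manifest$category, known)
    keep <- ani$query %in% known & ani$reference %in% known &
      ani$query != ani$reference
    ani <- ani[keep, , drop = FALSE]
    if (nrow(ani) > 0L) {
      # symmetrize: flag on max of the two directed values
      a <- pmin(ani$query, ani$reference)
      b <- pmax(ani$query, ani$reference)
      key <- paste(a, b, sep = "\r")
      best <- tapply(ani$ani_percent, key, max)
      pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
      hit <- best >= ani_threshold &
        cat_of[pairs[, 1L]] != cat_of[pairs[, 2L]]
      for (k in which(hit)) {
        g1 <- pairs[k, 1L]; g2 <- pairs[k, 2L]
        cross[[g1]] <- sort(union(cross[[g1]], g2))
        cross[[g2]] <- sort(union(cross[[g2]], g1))
      }
    }
  }

  genomes <- data.frame(
    genome_id = manifest$genome_id,
    category = manifest$category,
    path = manifest$path,
    length_bp = length_bp,
    n_contigs = n_contigs,
    is_cross_reactive = lengths(cross) > 0L,
    stringsAsFactors = FALSE)

  structure(list(genomes = genomes, cross_reactive_with = cross,
                 contigs = contigs, categories = categories,
                 ani_threshold = ani_threshold),
            class = "source_db")
}

#' @export
print.source_db <- function(x, ...) {
  cat(sprintf("source_db: %d genomes, %d categories, ANI threshold %g%%\n",
              nrow(x$genomes), nrow(x$categories), x$ani_threshold))
  for (i in seq_len(nrow(x$categories))) {
    cat_name <- x$categories$name[i]
    g <- x$genomes[x$genomes$category == cat_name, ]
    role <- x$categories$role[i]
    extra <- if (role == "aggregate_into")
      paste0(" -> ", x$categories$aggregate_target[i]) else ""
    cat(sprintf("  %-16s %-20s %3d genomes (%d cross-reactive)\n",
                cat_name, paste0("[", role, extra, "]"),
                nrow(g), sum(g$is_cross_reactive)))
  }
  invisible(x)
}

#' Source-specific genomes of a category
#'
#' The genomes of a fecal-source category that carry no cross-reactivity
#' flag; detection of at least one of these is the first condition for the
#' category to be called present.
#'
#' @param db a \code{source_db}.
#' @param category a fecal_source category name.
#' @return character vector of genome ids (possibly empty).
#' @export
specific_genomes <- function(db, category) {
  i <- match(category, db$categories$name)
  if (is.na(i)) stop("unknown category: ", category)
  if (db$categories$role[i] != "fecal_source") {
    stop("category is not a fecal_source: ", category)
  }
  g <- db$genomes
  g$genome_id[g$category == category & !g$is_cross_reactive]
}

# fecal-source category names (attribution/apportionment domain)
fecal_categories <- function(db) {
  db$categories$name[db$categories$role == "fecal_source"]
}

screen_category_of <- function(db) {
  s <- db$categories$name[db$categories$role == "environmental_screen"]
  if (length(s) == 0L) NULL else s
}

#' Serialize a source database
#'
#' Writes the manifest, flags, and category-role tables as TSVs so a
#' database round-trips losslessly through \code{\link{read_source_db}}.
#' Flags format: genome_id, category, flag (0/1), partner_ids
#' (semicolon-joined, "." when none).
#'
#' @param db a \code{source_db}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_source_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(db$genomes[, c("genome_id", "path", "category")],
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  partners <- vapply(db$cross_reactive_with, function(p) {
    if (length(p) == 0L) "." else paste(p, collapse = ";")
  }, "")
  flags <- data.frame(genome_id = db$genomes$genome_id,
                      category = db$genomes$category,
                      flag = as.integer(db$genomes$is_cross_reactive),
                      partner_ids = partners, stringsAsFactors = FALSE)
  write_tsv(flags, file.path(dir, "flags.tsv"),
            comment = sprintf("ani_threshold=%g", db$ani_threshold))
  write_tsv(db$categories, file.path(dir, "categories.tsv"))
  invisible(dir)
}

#' Read a serialized source database
#'
#' @param dir directory written by \code{\link{write_source_db}}.
#' @return a \code{source_db}.
#' @export
read_source_db <- function(dir) {
  manifest <- as_tsv_table(file.path(dir, "manifest.tsv"),
                           c("genome_id", "path", "category"))
  first <- readLines(file.path(dir, "flags.tsv"), n = 1L)
  thr <- as.numeric(sub("^# ani_threshold=", "", first))
  flags <- utils::read.delim(file.path(dir, "flags.tsv"), comment.char = "#",
                             stringsAsFactors = FALSE)
  cat_tab <- utils::read.delim(file.path(dir, "categories.tsv"),
                               stringsAsFactors = FALSE)
  screen <- cat_tab$name[cat_tab$role == "environmental_screen"]
  agg_rows <- cat_tab[cat_tab$role == "aggregate_into", , drop = FALSE]
  agg <- if (nrow(agg_rows) > 0L)
    stats::setNames(agg_rows$aggregate_target, agg_rows$name) else NULL
  db <- build_source_db(manifest, ani = NULL, ani_threshold = thr,
                        screen_category = if (length(screen) > 0L) screen else NULL,
                        aggregation_rules = agg)
  # restore flags
  flags$partner_ids <- as.character(flags$partner_ids)
  cross <- lapply(flags$partner_ids, function(p) {
    if (is.na(p) || p == ".") character(0)
    else sort(strsplit(p, ";", fixed = TRUE)[[1L]])
  })
  names(cross) <- flags$genome_id
  db$cross_reactive_with <- cross[db$genomes$genome_id]
  db$genomes$is_cross_reactive <- lengths(db$cross_reactive_with) > 0L
  # keep category order as serialized
  db$categories <- cat_tab[, c("name", "role", "aggregate_target")]
  db
}

#' Write the concatenated reference FASTA of a database
#'
#' All contigs of all genomes in one FASTA, for use as an aligner reference.
#'
#' @param db a \code{source_db}.
#' @param out output FASTA path.
#' @return \code{out}, invisibly.
#' @export
db_reference_fasta <- function(db, out) {
  sets <- lapply(db$genomes$path, Biostrings::readDNAStringSet)
  all <- do.call(c, sets)
  names(all) <- sub("\\s.*$", "", names(all))
  Biostrings::writeXStringSet(all, out)
  invisible(out)
}
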