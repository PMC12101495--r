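# Shared fixture builders: everything is generated in code at test time.

# Write a FASTA with one sequence and return its path.
write_fasta1 <- function(id, seq, dir = tempdir()) {
  path <- file.path(dir, paste0(id, ".fasta"))
  writeLines(c(paste0(">", id), seq), path)
  path
}

# Build a source_db from explicit sequences: seqs is a named character
# vector genome_id -> sequence, categories a same-named vector of category
# labels.
db_from_seqs <- function(seqs, categories, ani = NULL, ani_threshold = 95,
                         screen_category = NULL, aggregation_rules = NULL) {
  dir <- tempfile("db")
  dir.create(dir)
  paths <- vapply(names(seqs), function(id) write_fasta1(id, seqs[[id]], dir), "")
  manifest <- data.frame(genome_id = names(seqs), path = unname(paths),
                         category = unname(categories[names(seqs)]),
                         stringsAsFactors = FALSE)
  build_source_db(manifest, ani = ani, ani_threshold = ani_threshold,
                  screen_category = screen_category,
                  aggregation_rules = aggregation_rules)
}

# Hand-build a SAM file. records: data.frame with qname, flag, rname, pos,
# cigar, seq, nm (nm = NA to omit the tag). sq: named integer vector of
# reference lengths.
write_sam_fixture <- function(records, sq, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    fields <- c(r$qname, r$flag, r$rname, r$pos, 60L, r$cigar, "*", 0L, 0L,
                r$seq, strrep("I", nchar(r$seq)))
    if (!is.na(r$nm)) fields <- c(fields, paste0("NM:i:", r$nm))
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# A fixed-seed random sequence (independent of the package's generator
# internals beyond sample()).
fixed_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force per-base coverage depth oracle: materialize the
# coverage array position by position, trim extremes, average.
oracle_depth <- function(starts, ref_lens, genome_len, masking_percent) {
  cov <- integer(genome_len)
  for (i in seq_along(starts)) {
    to <- min(genome_len, starts[i] + ref_lens[i] - 1L)
    for (p in starts[i]:to) cov[p] <- cov[p] + 1L
  }
  n_trim <- floor(genome_len * masking_percent / 200)
  kept <- sort(cov)
  if (n_trim > 0L) kept <- kept[(n_trim + 1L):(genome_len - n_trim)]
  list(depth = mean(kept), breadth = mean(kept > 0L))
}

# Mix-design fixture shared by the acceptance tests: genomes, database with
# an environmental screen, and the spike-in fractions of the mixed design
# (10% wastewater + 5% each of five animal sources).
mix_fixture <- function(seed = 421L) {
  fr <- c(wastewater = 0.10, cat = 0.05, goat = 0.05, chicken = 0.05,
          cow = 0.05, dog = 0.05)
  g <- generate_genomes(
    c(wastewater = 3L, cat = 3L, goat = 3L, chicken = 3L, cow = 3L,
      dog = 3L, environmental = 4L),
    genome_len = 20000L, n_markers = 3L, marker_len = 400L, seed = seed)
  db <- build_source_db(g$manifest, ani = NULL,
                        screen_category = "environmental")
  list(genomes = g, db = db, fractions = fr)
}
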