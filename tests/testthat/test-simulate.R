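# Synthetic spike-in benchmark generator.

test_that("mixture cell fractions follow the density-times-volume model", {
  f <- true_cell_fractions(c(src = 1e6), c(src = 1),
                           rho_background = 1e6, volume_background = 9)
  expect_equal(unname(f["src"]), 0.1)
  expect_equal(attr(f, "background"), 0.9)
  # mixed design: 10% wastewater + 5% each of five sources, background 65%
  rho <- c(wastewater = 2e6, cat = 1e6, goat = 1e6, chicken = 1e6,
           cow = 1e6, dog = 1e6)
  vol <- c(wastewater = 5, cat = 5, goat = 5, chicken = 5, cow = 5, dog = 5)
  f2 <- true_cell_fractions(rho, vol, rho_background = 6.5e6,
                            volume_background = 10)
  expect_equal(as.numeric(f2),
               c(0.10, 0.05, 0.05, 0.05, 0.05, 0.05))
  expect_equal(attr(f2, "background"), 0.65)
  expect_equal(sum(f2) + attr(f2, "background"), 1)
  # a zero-volume source contributes nothing
  f3 <- true_cell_fractions(c(a = 1e6, b = 1e6), c(a = 1, b = 0),
                            rho_background = 1e6, volume_background = 1)
  expect_equal(unname(f3["b"]), 0)
  expect_error(true_cell_fractions(c(a = 0), c(a = 0), 0, 0), "no cells")
})

test_that("engineered shared species flag through the ANI engine", {
  g <- generate_genomes(c(pig = 2L, wastewater = 2L), genome_len = 6000L,
                        shared_species = data.frame(category_a = "pig",
                                                    category_b = "wastewater",
                                                    divergence = 0.02),
                        n_markers = 2L, marker_len = 300L, seed = 701)
  ani <- ani_all_pairs(g$manifest, fragment_len = 500)
  db <- build_source_db(g$manifest, ani = ani)
  flagged <- db$genomes$genome_id[db$genomes$is_cross_reactive]
  expect_length(flagged, 2L)
  expect_setequal(unique(db$genomes$category[db$genomes$is_cross_reactive]),
                  c("pig", "wastewater"))
  pair_ani <- ani$ani_percent[ani$query %in% flagged & ani$reference %in% flagged]
  expect_true(all(pair_ani >= 95))

  # divergence 0 gives an identical pair at ANI 100
  g0 <- generate_genomes(c(a = 1L, b = 1L), genome_len = 6000L,
                         shared_species = data.frame(category_a = "a",
                                                     category_b = "b",
                                                     divergence = 0),
                         n_markers = 0L, seed = 702)
  seqs <- vapply(g0$manifest$path, function(p)
    as.character(Biostrings::readDNAStringSet(p)[[1]]), "")
  expect_identical(unname(seqs[1]), unname(seqs[2]))
  expect_equal(estimate_ani(seqs[[1]], seqs[[2]])$ani_percent, 100)

  # no shared species -> zero flags
  g2 <- generate_genomes(c(a = 2L, b = 2L), genome_len = 6000L,
                         n_markers = 0L, seed = 703)
  db2 <- build_source_db(g2$manifest, ani = ani_all_pairs(g2$manifest,
                                                          fragment_len = 500))
  expect_false(any(db2$genomes$is_cross_reactive))
})

test_that("markers are embedded exactly once per genome at recorded coordinates", {
  g <- generate_genomes(c(a = 2L, b = 1L), genome_len = 8000L, n_markers = 3L,
                        marker_len = 300L, seed = 704)
  markers <- as.character(Biostrings::readDNAStringSet(g$marker_fasta))
  for (gid in g$manifest$genome_id) {
    s <- as.character(Biostrings::readDNAStringSet(
      g$manifest$path[g$manifest$genome_id == gid])[[1]])
    for (mi in seq_along(markers)) {
      row <- g$marker_coords[g$marker_coords$genome_id == gid &
                               g$marker_coords$marker_id == names(markers)[mi], ]
      expect_identical(substr(s, row$start, row$end), unname(markers[mi]))
      expect_identical(
        length(gregexpr(markers[mi], s, fixed = TRUE)[[1]]), 1L)
    }
  }
})

test_that("error-free reads parse to identity 100 and overlap 1", {
  g <- generate_genomes(c(a = 2L, environmental = 1L), genome_len = 5000L,
                        n_markers = 0L, seed = 705)
  db <- build_source_db(g$manifest)
  sim <- simulate_reads(g, c(a = 0.3), n_reads = 500, error_rate = 0, seed = 706)
  aln <- parse_alignments(sim$sam, db)
  expect_identical(nrow(aln), 500L)
  expect_true(all(aln$identity_percent == 100))
  expect_true(all(aln$overlap_fraction == 1))
  expect_true(all(aln$edit_distance == 0L))
})

test_that("read origins follow the spiked fractions within binomial noise", {
  g <- generate_genomes(c(a = 2L, environmental = 2L), genome_len = 5000L,
                        n_markers = 0L, seed = 707)
  n <- 100000L
  sim <- simulate_reads(g, c(a = 0.2), n_reads = n, error_rate = 0, seed = 708)
  prov <- utils::read.delim(sim$provenance, comment.char = "#")
  p_hat <- mean(prov$category == "a")
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p_hat - 0.2), 3 * se)
  # truth table carries the exact spiked fraction
  expect_equal(sim$ground_truth$true_cell_fraction[sim$ground_truth$category == "a"],
               0.2)
})

test_that("the recorded NM tag equals the true Hamming distance to the reference", {
  g <- generate_genomes(c(a = 1L, environmental = 1L), genome_len = 5000L,
                        n_markers = 0L, seed = 709)
  seqs <- stats::setNames(
    vapply(g$manifest$path, function(p)
      as.character(Biostrings::readDNAStringSet(p)[[1]]), ""),
    g$manifest$genome_id)
  sim <- simulate_reads(g, c(a = 0.5), n_reads = 200, error_rate = 0.02,
                        seed = 710)
  sam <- readLines(sim$sam)
  sam <- sam[!startsWith(sam, "@")]
  for (ln in sam[1:50]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    ref <- substr(seqs[[f[3]]], as.integer(f[4]),
                  as.integer(f[4]) + nchar(f[10]) - 1L)
    hamming <- sum(strsplit(f[10], "")[[1]] != strsplit(ref, "")[[1]])
    nm <- as.integer(sub("NM:i:", "", f[12]))
    expect_identical(nm, hamming)
  }
})

test_that("a fixed seed reproduces byte-identical FASTQ and SAM", {
  g <- generate_genomes(c(a = 2L, environmental = 1L), genome_len = 5000L,
                        n_markers = 2L, marker_len = 200L, seed = 711)
  s1 <- simulate_reads(g, c(a = 0.3), n_reads = 400, error_rate = 0.01,
                       seed = 712, dir = tempfile("rep1"))
  s2 <- simulate_reads(g, c(a = 0.3), n_reads = 400, error_rate = 0.01,
                       seed = 712, dir = tempfile("rep2"))
  expect_identical(readLines(s1$fastq), readLines(s2$fastq))
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  # seed recorded in headers
  expect_true(any(grepl("seed=712", readLines(s1$sam))))
})
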