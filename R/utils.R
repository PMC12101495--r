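# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases. Used by the synthetic-data generator; exported so
#' tests and examples can build tiny genomes without touching the generator.
#'
#' @param n sequence length in bp.
#' @return A single character string of A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Vectorized reverse complement on character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Apply i.i.d. substitutions at a fixed per-base rate to a character vector of
# equal-or-varying length sequences. Every substitution changes the base, so
# the number of substituted positions equals the Hamming distance introduced.
# Returns list(seq = mutated sequences, n_sub = substitutions per sequence).
mutate_seqs <- function(seqs, rate) {
  n <- length(seqs)
  lens <- nchar(seqs)
  n_sub <- stats::rbinom(n, lens, rate)
  hit <- which(n_sub > 0L)
  if (length(hit) == 0L) {
    return(list(seq = seqs, n_sub = n_sub))
  }
  out <- seqs
  for (i in hit) {
    L <- lens[i]
    pos <- sample.int(L, n_sub[i])
    chars <- strsplit(out[i], "", fixed = TRUE)[[1L]]
    cur <- chars[pos]
    # draw one of the three other bases for each position
    alt <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    chars[pos] <- alt
    out[i] <- paste(chars, collapse = "")
  }
  list(seq = out, n_sub = n_sub)
}

# Fast bulk substitution over many short equal-length reads: operates on the
# flattened character matrix so the per-read loop above is avoided.
mutate_reads <- function(reads, read_len, rate) {
  n <- length(reads)
  n_sub <- stats::rbinom(n, read_len, rate)
  if (all(n_sub == 0L)) {
    return(list(seq = reads, n_sub = n_sub))
  }
  flat <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
  # flat index of each substituted position
  idx <- unlist(lapply(which(n_sub > 0L), function(i) {
    (i - 1L) * read_len + sample.int(read_len, n_sub[i])
  }), use.names = FALSE)
  cur <- flat[idx]
  step <- sample.int(3L, length(idx), replace = TRUE)
  flat[idx] <- DNA_BASES[((match(cur, DNA_BASES) - 1L + step) %% 4L) + 1L]
  cols <- lapply(seq_len(read_len), function(p) flat[seq(p, by = read_len, length.out = n)])
  list(seq = do.call(paste0, cols), n_sub = n_sub)
}

# read a TSV (with or without a header line) or pass a data.frame through,
# enforcing the given column names
as_tsv_table <- function(x, col_names) {
  if (is.character(x) && length(x) == 1L) {
    first <- grep("^#", readLines(x, n = 10L), invert = TRUE, value = TRUE)[1L]
    has_header <- !is.na(first) &&
      all(col_names %in% strsplit(first, "\t", fixed = TRUE)[[1L]])
    x <- utils::read.delim(x, header = has_header, stringsAsFactors = FALSE,
                           comment.char = "#")
    if (has_header) return(check_cols(x, col_names))
    if (ncol(x) < length(col_names)) {
      stop("expected ", length(col_names), " columns: ",
           paste(col_names, collapse = ", "))
    }
    x <- x[, seq_along(col_names), drop = FALSE]
    names(x) <- col_names
  }
  check_cols(x, col_names)
}

check_cols <- function(x, col_names) {
  if (!is.data.frame(x)) stop("expected a data.frame or a TSV path")
  missing <- setdiff(col_names, names(x))
  if (length(missing) > 0L) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  x
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
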