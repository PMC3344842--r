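# Independent reference implementations and fixture builders used across
# the suite. These stay deliberately naive (quadratic DP, brute-force
# enumeration) so they can serve as oracles for the optimized paths.

# Reference affine-gap Smith-Waterman, full matrices, score only.
# A gap of length L costs gap_open + L * gap_extend.
sw_score_ref <- function(query, target, matrix = blosum62(),
                         gap_open = 11, gap_extend = 1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  m <- length(q); n <- length(t)
  NEG <- -1e6
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             E[i + 1, j] - gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             F[i, j + 1] - gap_extend)
      h <- max(0, H[i, j] + matrix[q[i], t[j]],
               E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

# brute-force enumeration of all K-mer occurrences in a protein string
# (no X/* allowed in a key), returning 0-based offsets per key
kmer_scan_ref <- function(residues, K) {
  n <- nchar(residues)
  if (n < K) return(list())
  offs <- 0:(n - K)
  keys <- substring(residues, offs + 1, offs + K)
  ok <- !grepl("[X*|]", keys)
  split(offs[ok], keys[ok])
}

random_protein <- function(n) {
  paste(sample(ghostseek:::GS_AA, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny in-memory db + reads fixture at a given identity
tiny_fixture <- function(n_db = 30, n_reads = 15, identity = 1.0,
                         indel = 0, seed = 42) {
  spec <- synthetic_spec(n_db_seqs = n_db, db_len_range = c(80L, 160L),
                         n_reads = n_reads, target_identity = identity,
                         indel_rate = indel, seed = seed)
  db <- generate_db(spec)
  gr <- generate_reads(db, spec)
  list(spec = spec, db = db, reads = gr$reads, truth = gr$truth)
}

one_read_df <- function(id, bases, quals = NULL) {
  df <- data.frame(id = id, bases = bases, stringsAsFactors = FALSE)
  df$quals <- list(quals)
  df
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
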