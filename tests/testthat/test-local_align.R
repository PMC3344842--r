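test_that("window_bounds applies the m + 2r + 2e formula with clipping", {
  wb <- window_bounds(100L, m = 25L, r = 4L, e = 2L, seq_start = 0L,
                      seq_end = 1000L)
  expect_equal(unname(wb[1, "hi"] - wb[1, "lo"]), 37L)  # 25 + 2*4 + 2*2
  wb0 <- window_bounds(100L, m = 20L, r = 4L, e = 0L, seq_start = 0L,
                       seq_end = 1000L)
  expect_equal(unname(wb0[1, "hi"] - wb0[1, "lo"]), 28L)
  clipped <- window_bounds(0L, m = 25L, r = 4L, e = 2L, seq_start = 0L,
                           seq_end = 1000L)
  expect_equal(unname(clipped[1, "lo"]), 0L)
  expect_lt(clipped[1, "hi"] - clipped[1, "lo"], 37L)
})

test_that("smith_waterman scores identities as diagonal matrix sums", {
  # independent route: read the diagonal entries straight from the file
  raw <- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
                                       package = "ghostseek"))
  want <- sum(diag(raw[c("M", "K", "W", "V"), c("M", "K", "W", "V")]))
  aln <- smith_waterman("MKWV", "MKWV")
  expect_equal(aln$score, want)
  expect_equal(aln$matches, 4L)
  expect_equal(aln$q_interval, c(0L, 4L))

  # nothing scores positively against a stop-only target
  zero <- smith_waterman("MKWVLL", "******")
  expect_equal(zero$score, 0L)
  expect_equal(zero$align_len, 0L)

  expect_error(smith_waterman("", "MK"), "non-empty")
})

test_that("smith_waterman agrees with the reference DP on random pairs", {
  set.seed(41)
  for (i in 1:25) {
    a <- random_protein(sample(8:25, 1))
    b <- random_protein(sample(8:40, 1))
    got <- smith_waterman(a, b)
    expect_equal(got$score, sw_score_ref(a, b), info = paste(a, b))
    # symmetry
    expect_equal(smith_waterman(b, a)$score, got$score)
    # alignment statistics are internally consistent
    expect_equal(got$align_len,
                 got$matches + got$mismatches + got$gaps)
    expect_true(diff(got$q_interval) <= nchar(a))
  }
})

test_that("gap costs follow the open + L * extend convention", {
  # query with an inserted residue relative to target forces one gap
  target <- "MKWVRHEDAC"
  query <- "MKWVRAHEDAC"  # A inserted after position 5
  got <- smith_waterman(query, target, gap_open = 5L, gap_extend = 1L)
  expect_equal(got$score,
               sw_score_ref(query, target, gap_open = 5, gap_extend = 1))
  expect_equal(got$gap_openings, 1L)
  expect_equal(got$gaps, 1L)
})

test_that("bit_score applies the Karlin-Altschul conversion", {
  expect_equal(bit_score(0), (0 - log(0.041)) / log(2), tolerance = 1e-12)
  expect_equal(bit_score(0), 4.61, tolerance = 0.01)
  expect_equal(bit_score(100), 43.1, tolerance = 0.05)
  raws <- 0:200
  expect_true(all(diff(bit_score(raws)) > 0))
  expect_error(bit_score(10, lambda = 0), "positive")
  expect_error(bit_score(10, k_const = -1), "positive")
  # raw_for_bits inverts the conversion
  expect_true(all(bit_score(ghostseek:::raw_for_bits(c(20, 50))) >=
                    c(20, 50)))
})

test_that("align_candidates recovers identity hits at 100%", {
  set.seed(47)
  seqs <- vapply(c(60, 80, 50), random_protein, "")
  ch <- ghostseek:::make_chunk(1L, c("a", "b", "c"), seqs, 4L)
  # a read encoding residues 10..29 of sequence b, exactly
  frag <- substring(seqs[2], 11, 30)
  dna <- paste(vapply(strsplit(frag, "")[[1]], function(a) {
    ghostseek:::codon_choices()[[a]][1]
  }, ""), collapse = "")
  tf <- translate_frame(dna, 1L)
  tf$read_id <- "r1"
  params <- search_params()
  cands <- find_candidates(query_keys(tf, 4, 2), ch, params$r, params$t)
  hits <- align_candidates(tf, cands, ch, params)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$subject_id, "b")
  expect_equal(hits$identity_pct, 100)
  expect_equal(hits$raw_score, smith_waterman(frag, frag)$score)
  expect_equal(hits$s_start, 10L)
  expect_equal(hits$s_end, 30L)
  expect_equal(hits$q_dna_start, 0L)
  expect_equal(hits$q_dna_end, 60L)
})

test_that("window restriction never beats the full Smith-Waterman score,
           and matches it for on-diagonal ungapped truths", {
  set.seed(53)
  params <- search_params(t = 1, s = 1)
  for (i in 1:15) {
    subject <- random_protein(sample(80:150, 1))
    ch <- ghostseek:::make_chunk(1L, "s", subject, 4L)
    # read encodes an exact fragment: ungapped truth on the diagonal
    start <- sample(1:(nchar(subject) - 21), 1)
    frag <- substring(subject, start, start + 20)
    dna <- paste(vapply(strsplit(frag, "")[[1]], function(a) {
      ch_ <- ghostseek:::codon_choices()[[a]]
      ch_[sample.int(length(ch_), 1)]
    }, ""), collapse = "")
    tf <- translate_frame(dna, 1L)
    tf$read_id <- "r"
    cands <- find_candidates(query_keys(tf, 4, 1), ch, params$r, params$t)
    hits <- align_candidates(tf, cands, ch, params, min_raw = 1L)
    full <- smith_waterman(tf$residues, subject)$score
    expect_true(all(hits$raw_score <= full))
    # the candidate on the true diagonal recovers the full score
    expect_equal(max(hits$raw_score), full)
  }
})
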