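test_that("generate_db is deterministic with background composition", {
  spec <- synthetic_spec(n_db_seqs = 300, db_len_range = c(100, 300),
                         seed = 1)
  db1 <- generate_db(spec)
  db2 <- generate_db(spec)
  expect_identical(db1, db2)
  expect_equal(nrow(db1), 300L)
  lens <- nchar(db1$residues)
  expect_true(all(lens >= 100 & lens <= 300))

  # residue composition matches the stated background frequencies
  counts <- table(factor(strsplit(paste(db1$residues, collapse = ""),
                                  "")[[1]], levels = ghostseek:::GS_AA))
  chi <- suppressWarnings(
    stats::chisq.test(as.vector(counts), p = ghostseek:::GS_BG_FREQ))
  expect_gt(chi$p.value, 1e-4)

  expect_equal(nrow(generate_db(synthetic_spec(n_db_seqs = 0))), 0L)
})

test_that("generate_reads honours identity, strand, and frame bookkeeping", {
  spec <- synthetic_spec(n_db_seqs = 60, db_len_range = c(100, 300),
                         n_reads = 200, target_identity = c(0.6, 0.9),
                         indel_rate = 0.005, seed = 8)
  db <- generate_db(spec)
  gr <- generate_reads(db, spec)
  gr2 <- generate_reads(db, spec)
  expect_identical(gr, gr2)

  lens <- nchar(gr$reads$bases)
  expect_true(all(lens >= 60 & lens <= 75))
  expect_true(all(lengths(gr$reads$quals) == lens))

  # realized identity is recorded and sits inside the target range,
  # up to rounding at fragment size (~1/20)
  expect_true(all(gr$truth$realized_identity >= 0.55 &
                    gr$truth$realized_identity <= 1))
  expect_equal(mean(gr$truth$realized_identity), 0.75, tolerance = 0.05)

  # strand balance is binomial around one half
  n_fwd <- sum(gr$truth$frame == 1L)
  expect_gt(stats::binom.test(n_fwd, nrow(gr$truth))$p.value, 1e-4)
})

test_that("identity-1 reads translate to exact substrings of their source", {
  fx <- tiny_fixture(n_db = 20, n_reads = 25, identity = 1, seed = 3)
  for (i in seq_len(nrow(fx$truth))) {
    tr <- fx$truth[i, ]
    tf <- translate_frame(fx$reads$bases[i], tr$frame)
    src <- fx$db$residues[fx$db$id == tr$subject_id]
    expect_true(grepl(tf$residues, src, fixed = TRUE), info = tr$read_id)
    # and the recorded interval is where it sits
    expect_equal(substring(src, tr$subject_start,
                           tr$subject_start + nchar(tf$residues) - 1L),
                 tf$residues)
  }
})

test_that("full_sw_search finds planted fragments and is order-invariant", {
  fx <- tiny_fixture(n_db = 15, n_reads = 10, identity = 1, seed = 25)
  oracle <- full_sw_search(fx$reads, fx$db)
  expect_equal(oracle$subject_id, fx$truth$subject_id)
  expect_true(all(oracle$raw_score > 0))
  # permuting read order permutes results identically
  perm <- sample(nrow(fx$reads))
  oracle_p <- full_sw_search(fx$reads[perm, ], fx$db)
  expect_equal(oracle_p$read_id, oracle$read_id[perm])
  expect_equal(oracle_p$raw_score, oracle$raw_score[perm])
  # oracle scores match the reference DP on the best subject
  for (i in 1:3) {
    best <- max(vapply(six_frame_translate(fx$reads$bases[i]), function(tf) {
      if (nchar(tf$residues) == 0) return(0)
      max(vapply(fx$db$residues, function(s) {
        sw_score_ref(tf$residues, s)
      }, 0))
    }, 0))
    expect_equal(oracle$raw_score[i], best)
  }
})

test_that("restricted pipeline scores never exceed the oracle", {
  fx <- tiny_fixture(n_db = 15, n_reads = 12, identity = 0.8, seed = 27)
  hits <- search_reads(fx$reads, build_chunks(fx$db), min_bits = 5)
  oracle <- full_sw_search(fx$reads, fx$db)
  by_read <- setNames(oracle$raw_score, oracle$read_id)
  expect_true(all(hits$raw_score <= by_read[hits$read_id]))
})

test_that("sensitivity_curve handles the degenerate cases", {
  oracle <- data.frame(read_id = c("a", "b", "c"),
                       subject_id = c("s1", "s2", "s3"),
                       raw_score = c(120L, 140L, 160L),  # all >= 50 bits
                       bit_score = bit_score(c(120, 140, 160)),
                       stringsAsFactors = FALSE)
  oracle$tie_subjects <- list("s1", "s2", "s3")
  # tool output identical to the oracle: 100% in every populated bin
  tool <- data.frame(read_id = oracle$read_id,
                     subject_id = oracle$subject_id,
                     raw_score = oracle$raw_score,
                     bit_score = oracle$bit_score,
                     stringsAsFactors = FALSE)
  sc <- sensitivity_curve(tool, oracle)
  expect_true(all(sc$recall[sc$n_oracle > 0] == 1))
  expect_equal(sum(sc$n_oracle), 3L)
  # empty tool output: 0% everywhere it counts
  sc0 <- sensitivity_curve(tool[0, ], oracle)
  expect_true(all(sc0$recall[sc0$n_oracle > 0] == 0))
  expect_error(sensitivity_curve(tool, oracle, bins = c(50, 40)),
               "increasing")
  rc <- recall_vs_oracle(tool, oracle, min_bits = 50)
  expect_equal(rc$recall_pct, 100)
  expect_equal(rc$n_eligible, 3L)
})
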