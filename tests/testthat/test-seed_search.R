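test_that("query_keys samples offsets with skip s and drops X/* keys", {
  frame <- list(residues = random_protein(25))
  expect_equal(nrow(query_keys(frame, 4, 2)), 11L)  # offsets 0,2,...,20
  expect_equal(query_keys(frame, 4, 2)$offset, seq(0L, 20L, 2L))
  expect_equal(nrow(query_keys(frame, 4, 1)), 22L)
  expect_equal(nrow(query_keys(list(residues = "MXKL"), 4, 1)), 0L)
  expect_equal(nrow(query_keys(list(residues = "MK"), 4, 1)), 0L)
  # keys match the substring they claim to be
  qk <- query_keys(frame, 4, 3)
  expect_equal(qk$key, substring(frame$residues, qk$offset + 1,
                                 qk$offset + 4))
})

test_that("a query identical to a database sequence yields one candidate
           on the diagonal", {
  seqs <- c(random_protein(40), random_protein(25), random_protein(35))
  ch <- ghostseek:::make_chunk(1L, c("a", "b", "c"), seqs, 4L)
  keys <- query_keys(list(residues = seqs[2]), 4, 1)
  cands <- find_candidates(keys, ch, r = 4, t = 1)
  cands <- cands[cands$db_seq_id == "b", ]
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$align_start, ch$seq_table$start[2])
  expect_equal(cands$support, nrow(keys))  # all 22 k-mers on one diagonal
})

test_that("region-pair bucketing follows the hand-traced rule", {
  bucket <- ghostseek:::bucket_candidates
  # both starts in bucket 0 -> one candidate, support 2
  out <- bucket(d = c(0L, 3L), b = c(0L, 3L) %/% 4L, t = 2L)
  expect_equal(out, data.frame(align_start = 0L, support = 2L))
  # starts 3 and 5 fall in buckets 0 and 1: adjacent-region rule fires
  out2 <- bucket(d = c(3L, 5L), b = c(3L, 5L) %/% 4L, t = 2L)
  expect_equal(out2, data.frame(align_start = 3L, support = 2L))
  # below threshold: nothing
  expect_equal(nrow(bucket(d = c(3L, 12L), b = c(3L, 12L) %/% 4L, t = 2L)),
               0L)
  # matches in buckets 0,1,2: pairs (0,1) and (1,2) are emitted, but the
  # pair anchored at bucket 2 adds no uncovered bucket and is skipped
  out3 <- bucket(d = c(1L, 5L, 9L), b = c(1L, 5L, 9L) %/% 4L, t = 2L)
  expect_equal(out3$align_start, c(1L, 5L))
  expect_equal(out3$support, c(2L, 2L))
  # negative predicted starts bucket with floor division
  out4 <- bucket(d = c(-2L, 1L), b = c(-2L, 1L) %/% 4L, t = 2L)
  expect_equal(out4$align_start, -2L)
  expect_equal(out4$support, 2L)
})

test_that("find_candidates validates parameters", {
  ch <- ghostseek:::make_chunk(1L, "a", random_protein(30), 4L)
  keys <- query_keys(list(residues = random_protein(20)), 4, 1)
  expect_error(find_candidates(keys, ch, r = 0, t = 1), "r must be")
  expect_error(find_candidates(keys, ch, r = 4, t = 0), "t must be")
})

test_that("candidates at stricter settings are covered at looser ones", {
  set.seed(23)
  db <- data.frame(id = sprintf("s%d", 1:8),
                   residues = vapply(rep(120, 8), random_protein, ""),
                   stringsAsFactors = FALSE)
  reads <- data.frame(id = sprintf("r%d", 1:10),
                      bases = vapply(rep(66, 10), random_dna, ""),
                      stringsAsFactors = FALSE)
  covers <- function(loose, strict, r) {
    # every strict candidate has a loose candidate on the same subject
    # anchored within one region of it
    all(vapply(seq_len(nrow(strict)), function(i) {
      same <- loose[loose$db_seq_id == strict$db_seq_id[i], ]
      nrow(same) > 0 &&
        any(abs(same$align_start - strict$align_start[i]) <= 2 * r)
    }, TRUE))
  }
  for (i in seq_len(nrow(reads))) {
    frames <- six_frame_translate(reads$bases[i])
    for (tf in frames[c(1, 4)]) {
      cand <- function(K, s, t) {
        ch <- ghostseek:::make_chunk(1L, db$id, db$residues, K)
        find_candidates(query_keys(tf, K, s), ch, r = 4, t = t)
      }
      c_t1 <- cand(3, 1, 1); c_t2 <- cand(3, 1, 2); c_t3 <- cand(3, 1, 3)
      expect_true(covers(c_t1, c_t2, 4))
      expect_true(covers(c_t2, c_t3, 4))
      c_s2 <- cand(3, 2, 1); c_s4 <- cand(3, 4, 1)
      expect_true(covers(c_t1, c_s2, 4))
      expect_true(covers(c_s2, c_s4, 4))
      # smaller K never yields fewer key matches -> coverage again
      c_k4 <- cand(4, 1, 1)
      expect_true(covers(c_t1, c_k4, 4))
    }
  }
})

test_that("candidate supports never span a database delimiter", {
  set.seed(31)
  db <- data.frame(id = c("a", "b"),
                   residues = rep(random_protein(60), 2),  # identical twins
                   stringsAsFactors = FALSE)
  ch <- ghostseek:::make_chunk(1L, db$id, db$residues, 4L)
  keys <- query_keys(list(residues = db$residues[1]), 4, 1)
  cands <- find_candidates(keys, ch, r = 4, t = 1)
  expect_equal(sort(cands$db_seq_id), c("a", "b"))
  st <- ch$seq_table$start[cands$db_seq]
  en <- st + ch$seq_table$length[cands$db_seq]
  expect_true(all(cands$align_start >= st - 25 & cands$align_start < en))
  # supports are per sequence: each twin gets the full diagonal count
  expect_equal(cands$support, rep(nrow(keys), 2))
})

test_that("count_candidates matches find_candidates totals", {
  fx <- tiny_fixture(n_db = 12, n_reads = 5, identity = 1, seed = 9)
  params <- search_params()
  chunks <- build_chunks(fx$db, params)
  counts <- count_candidates(fx$reads, chunks, params)
  manual <- vapply(seq_len(nrow(fx$reads)), function(i) {
    tot <- 0L
    for (tf in six_frame_translate(fx$reads$bases[i])) {
      keys <- query_keys(tf, params$K, params$s)
      for (ch in chunks) tot <- tot + nrow(find_candidates(keys, ch,
                                                           params$r,
                                                           params$t))
    }
    tot
  }, 0L)
  expect_equal(unname(counts), manual)
  expect_true(all(counts >= 1L))  # identity-1 reads always seed
  # a read with no key matches yields zero
  none <- data.frame(id = "z", bases = strrep("A", 60),
                     stringsAsFactors = FALSE)
  ch1 <- ghostseek:::make_chunk(1L, "w", strrep("W", 50), 4L)
  expect_equal(unname(count_candidates(none, list(ch1), params)), 0L)
})
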