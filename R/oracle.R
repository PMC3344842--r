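# Exhaustive Smith-Waterman oracle (SSEARCH-style ground truth) and the
# sensitivity evaluation comparing tool hits against it.

# concatenate a database with delimiters, without building an index
db_concat <- function(db) {
  codes <- lapply(db$residues, encode_residues)
  lens <- lengths(codes)
  n <- length(codes)
  pieces <- vector("list", max(2L * n - 1L, 0L))
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- codes
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- list(GS_DELIM)
  list(concat = unlist(pieces, use.names = FALSE),
       ids = db$id, lens = lens)
}

#' Exhaustive Smith-Waterman search (the sensitivity oracle)
#'
#' For each read, computes the best unrestricted Smith-Waterman local
#' alignment score over all six reading frames and every database
#' sequence, with the same substitution matrix, gap penalties, and bit
#' conversion as the restricted pipeline. Used as ground truth when
#' measuring the sensitivity of the seeded search.
#'
#' @param reads Reads data frame (`id`, `bases`).
#' @param db Protein records data frame (`id`, `residues`).
#' @param params A [search_params()] (matrix and gap penalties are used).
#' @param lenient Passed to the translator.
#' @return Data frame with one row per read: `read_id`, `subject_id`
#'   (best subject, first in database order), `frame`, `raw_score`,
#'   `bit_score`, and a list-column `tie_subjects` holding every subject
#'   achieving the maximal score in any frame.
#' @export
full_sw_search <- function(reads, db, params = search_params(),
                           lenient = FALSE) {
  stopifnot(nrow(db) > 0L)
  cc <- db_concat(db)
  matrix <- resolve_matrix(params)
  n <- nrow(reads)
  out <- data.frame(read_id = reads$id, subject_id = NA_character_,
                    frame = NA_integer_, raw_score = 0L,
                    bit_score = bit_score(0), stringsAsFactors = FALSE)
  ties <- vector("list", n)
  delim0 <- GS_DELIM - 1L
  concat0 <- cc$concat - 1L
  for (i in seq_len(n)) {
    frames <- suppressWarnings(
      six_frame_translate(reads$bases[i], lenient = lenient))
    best <- 0L
    best_frame <- NA_integer_
    best_sub <- NA_character_
    tie <- character(0)
    for (tf in frames) {
      if (nchar(tf$residues) == 0L) next
      v <- sw_scan_best(encode_residues(tf$residues) - 1L, concat0,
                        matrix, params$gap_open, params$gap_extend, delim0)
      mx <- max(v)
      if (mx > best) {
        best <- mx
        best_frame <- tf$frame
        best_sub <- cc$ids[which.max(v)]
        tie <- cc$ids[v == mx]
      } else if (mx == best && best > 0L) {
        tie <- union(tie, cc$ids[v == mx])
      }
    }
    out$raw_score[i] <- best
    out$frame[i] <- best_frame
    out$subject_id[i] <- best_sub
    ties[[i]] <- tie
  }
  out$bit_score <- bit_score(out$raw_score)
  out$tie_subjects <- ties
  out
}

#' Sensitivity of tool hits relative to the oracle, by bit-score bin
#'
#' A read counts as recovered when any of the tool's best hits (rank-1
#' ties included) names a subject in the oracle's best-hit tie set.
#' Fractions are reported per oracle-bit-score bin.
#'
#' @param tool_hits Hits data frame from [search_reads()] /
#'   [search_all()].
#' @param oracle_hits Oracle table from [full_sw_search()].
#' @param bins Increasing numeric bin edges over oracle bit scores;
#'   default: width-10 bins starting at 20, covering the observed range.
#' @return Data frame with `bin_lo`, `bin_hi`, `n_oracle`, `n_recovered`,
#'   `recall` (fraction in `[0, 1]`, `NA` for empty bins).
#' @export
sensitivity_curve <- function(tool_hits, oracle_hits, bins = NULL) {
  if (is.null(bins)) {
    top <- max(oracle_hits$bit_score, 30)
    bins <- seq(20, 10 * ceiling(top / 10) + 10, by = 10)
  }
  if (is.unsorted(bins, strictly = TRUE)) {
    stop("bins must be strictly increasing")
  }
  rec <- recovered_reads(tool_hits, oracle_hits)
  lo <- bins[-length(bins)]
  hi <- bins[-1L]
  n_or <- integer(length(lo))
  n_rec <- integer(length(lo))
  for (j in seq_along(lo)) {
    in_bin <- oracle_hits$bit_score >= lo[j] & oracle_hits$bit_score < hi[j]
    n_or[j] <- sum(in_bin)
    n_rec[j] <- sum(in_bin & rec)
  }
  data.frame(bin_lo = lo, bin_hi = hi, n_oracle = n_or, n_recovered = n_rec,
             recall = ifelse(n_or > 0L, n_rec / n_or, NA_real_))
}

# logical vector over oracle rows: tool best hit names an oracle tie subject
recovered_reads <- function(tool_hits, oracle_hits) {
  tb <- best_hits(tool_hits)
  tool_subjects <- split(tb$subject_id, tb$read_id)
  vapply(seq_len(nrow(oracle_hits)), function(i) {
    ts <- tool_subjects[[oracle_hits$read_id[i]]]
    !is.null(ts) && length(intersect(ts, oracle_hits$tie_subjects[[i]])) > 0L
  }, FALSE)
}

#' Overall recall against the oracle above a bit-score threshold
#'
#' @inheritParams sensitivity_curve
#' @param min_bits Restrict to reads whose oracle best hit reaches this
#'   bit score (default 50, the conventional "not by chance" cutoff).
#' @return A list with `recall_pct` (percentage), `n_eligible`, and
#'   `n_recovered`.
#' @export
recall_vs_oracle <- function(tool_hits, oracle_hits, min_bits = 50) {
  elig <- oracle_hits$bit_score >= min_bits & oracle_hits$raw_score > 0L
  rec <- recovered_reads(tool_hits, oracle_hits)
  list(recall_pct = 100 * sum(rec & elig) / max(sum(elig), 1L),
       n_eligible = sum(elig), n_recovered = sum(rec & elig))
}
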