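# Window-restricted Smith-Waterman scoring of candidates, plus the
# Karlin-Altschul raw -> bit score conversion.

# Default gapped Karlin-Altschul parameters for BLOSUM62 with gap
# penalties 11/1, and the default reporting threshold (~20 bits).
GS_LAMBDA <- 0.267
GS_KCONST <- 0.041

#' Convert a raw alignment score to a bit score
#'
#' Standard Karlin-Altschul conversion
#' `bits = (lambda * raw - ln k) / ln 2`, with the gapped BLOSUM62 11/1
#' parameters as defaults.
#'
#' @param raw Raw alignment score(s), non-negative.
#' @param lambda Karlin-Altschul lambda (> 0).
#' @param k_const Karlin-Altschul K (> 0).
#' @return Numeric bit score(s), strictly increasing in `raw`.
#' @export
#' @examples
#' bit_score(100)  # ~43.1 bits
bit_score <- function(raw, lambda = GS_LAMBDA, k_const = GS_KCONST) {
  if (lambda <= 0 || k_const <= 0) stop("lambda and k must be positive")
  (lambda * raw - log(k_const)) / log(2)
}

# inverse: smallest integer raw score reaching `bits`
raw_for_bits <- function(bits, lambda = GS_LAMBDA, k_const = GS_KCONST) {
  as.integer(ceiling((bits * log(2) + log(k_const)) / lambda))
}

#' Alignment window around a candidate position
#'
#' The window spans `align_start - (r + e)` to `align_start + m + r + e`
#' (size `m + 2r + 2e`), clipped to the candidate's source sequence so it
#' never crosses a delimiter.
#'
#' @param align_start Predicted alignment start, concatenated coordinates.
#' @param m Translated query length (residues).
#' @param r,e Region size and extension (see [search_params()]).
#' @param seq_start,seq_end 0-based half-open bounds of the source
#'   sequence in the concatenated database.
#' @return Integer `c(lo, hi)`, 0-based half-open in concat coordinates.
#' @export
window_bounds <- function(align_start, m, r, e, seq_start, seq_end) {
  lo <- pmax(seq_start, align_start - (r + e))
  hi <- pmin(seq_end, align_start + m + r + e)
  cbind(lo = lo, hi = pmax(hi, lo))
}

#' Smith-Waterman local alignment of two protein strings
#'
#' Optimal local alignment under affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`). `X` is scored from the matrix's X
#' column; `*` scores the matrix minimum against everything. A score-0
#' result returns empty intervals.
#'
#' @param query,target Protein strings (may contain `X` and `*`).
#' @param matrix Substitution matrix on the internal alphabet
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `score`, 0-based half-open `q_interval` and
#'   `s_interval`, `align_len`, `matches`, `mismatches`, `gap_openings`,
#'   `gaps`.
#' @export
#' @examples
#' smith_waterman("MKWV", "MKWV")$score  # sum of 4 diagonal BLOSUM62 entries
smith_waterman <- function(query, target, matrix = blosum62(),
                           gap_open = 11L, gap_extend = 1L) {
  if (nchar(query) == 0L || nchar(target) == 0L) {
    stop("query and target must be non-empty")
  }
  res <- sw_align_cpp(encode_residues(query) - 1L,
                      encode_residues(target) - 1L,
                      matrix, as.integer(gap_open), as.integer(gap_extend))
  list(score = res$score,
       q_interval = c(res$q_start, res$q_end),
       s_interval = c(res$s_start, res$s_end),
       align_len = res$align_len, matches = res$matches,
       mismatches = res$mismatches, gap_openings = res$gap_openings,
       gaps = res$gaps)
}

#' Score candidates of one frame with window-restricted Smith-Waterman
#'
#' Runs the full query frame against the `m + 2r + 2e` window around each
#' candidate and assembles hits for alignments whose raw score reaches
#' `min_raw`. Subject coordinates are mapped back to source-sequence
#' protein coordinates and query coordinates to forward-strand DNA
#' positions on the read (via [back_map()]).
#'
#' @param frame A `translated_frame` of the read.
#' @param cands Candidate data frame from [find_candidates()].
#' @param chunk The `index_chunk` the candidates refer to.
#' @param params A [search_params()].
#' @param min_raw Minimum raw score to report.
#' @param matrix Substitution matrix (defaults to the params matrix).
#' @return A hits data frame (0-based internal coordinates), one row per
#'   reported candidate alignment.
#' @export
align_candidates <- function(frame, cands, chunk, params = search_params(),
                             min_raw = raw_for_bits(20), matrix = NULL) {
  if (is.null(matrix)) matrix <- resolve_matrix(params)
  empty <- empty_hits()
  if (nrow(cands) == 0L || nchar(frame$residues) == 0L) return(empty)
  m <- nchar(frame$residues)
  st <- chunk$seq_table$start[cands$db_seq]
  en <- st + chunk$seq_table$length[cands$db_seq]
  wb <- window_bounds(cands$align_start, m, params$r, params$e, st, en)
  stats <- sw_align_batch(encode_residues(frame$residues) - 1L,
                          chunk$concat - 1L, wb[, "lo"], wb[, "hi"],
                          matrix, params$gap_open, params$gap_extend)
  keep <- which(stats[, "score"] >= min_raw & stats[, "score"] > 0L)
  if (length(keep) == 0L) return(empty)
  stats <- stats[keep, , drop = FALSE]
  q_aa_start <- stats[, "q_start"]
  q_aa_len <- stats[, "q_end"] - q_aa_start
  dna <- vapply(seq_along(keep), function(i) {
    back_map(frame$frame, q_aa_start[i], q_aa_len[i], frame$dna_length)
  }, integer(2))
  s_abs_start <- wb[keep, "lo"] + stats[, "s_start"] - st[keep]
  data.frame(
    read_id = if (is.null(frame$read_id)) NA_character_ else frame$read_id,
    frame = frame$frame,
    subject_id = cands$db_seq_id[keep],
    raw_score = stats[, "score"],
    bit_score = bit_score(stats[, "score"]),
    identity_pct = 100 * stats[, "matches"] / stats[, "align_len"],
    align_len = stats[, "align_len"],
    mismatches = stats[, "mismatches"],
    gap_openings = stats[, "gap_openings"],
    q_dna_start = dna[1L, ],
    q_dna_end = dna[2L, ],
    s_start = as.integer(s_abs_start),
    s_end = as.integer(s_abs_start + (stats[, "s_end"] - stats[, "s_start"])),
    q_aa_start = q_aa_start,
    q_aa_len = q_aa_len,
    stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(read_id = character(0), frame = integer(0),
             subject_id = character(0), raw_score = integer(0),
             bit_score = numeric(0), identity_pct = numeric(0),
             align_len = integer(0), mismatches = integer(0),
             gap_openings = integer(0), q_dna_start = integer(0),
             q_dna_end = integer(0), s_start = integer(0),
             s_end = integer(0), q_aa_start = integer(0),
             q_aa_len = integer(0), stringsAsFactors = FALSE)
}
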