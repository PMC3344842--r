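# Candidate search: skip-sampled query keys are matched against the chunk
# index; each match at database position p with query offset q predicts an
# alignment start d = p - q. Predicted starts are bucketed into regions of
# size r; a region pair (b, b+1) holding at least t matches yields a
# candidate anchored at the smallest contributing d. Overlapping
# qualifying pairs are merged so a database region is aligned only once.

#' Generate skip-sampled query keys for one translated frame
#'
#' Keys are taken at offsets `0, s, 2s, ...` up to `length - K`; keys
#' containing `X` or `*` are omitted.
#'
#' @param frame A `translated_frame` (or a plain residue string).
#' @param K Seed length.
#' @param s Skip between successive offsets.
#' @return Data frame with `offset` (0-based query offset), `key`
#'   (residue string) and `code` (internal integer key code).
#' @export
query_keys <- function(frame, K, s) {
  residues <- if (is.character(frame)) frame else frame$residues
  codes <- encode_residues(residues)
  n <- length(codes)
  empty <- data.frame(offset = integer(0), key = character(0),
                      code = integer(0), stringsAsFactors = FALSE)
  if (n < K) return(empty)
  offs <- seq.int(0L, n - K, by = s)
  kc <- kmer_codes(codes, K)[offs + 1L]
  keep <- !is.na(kc)
  if (!any(keep)) return(empty)
  offs <- offs[keep]
  data.frame(
    offset = offs,
    key = substring(residues, offs + 1L, offs + K),
    code = kc[keep],
    stringsAsFactors = FALSE)
}

#' Find candidate alignment positions for a set of query keys
#'
#' @param keys Data frame from [query_keys()].
#' @param chunk An `index_chunk` built with the same `K`.
#' @param r Region size (residues); must be positive.
#' @param t Minimum seed matches in a region plus its right neighbour.
#' @return Data frame of candidates: `chunk_id`, `db_seq` (1-based row in
#'   the chunk's `seq_table`), `db_seq_id`, `align_start` (predicted start
#'   in concatenated coordinates; may precede the sequence start before
#'   clipping), and `support` (seed-match count).
#' @export
find_candidates <- function(keys, chunk, r, t) {
  if (r <= 0L) stop("region size r must be positive")
  if (t < 1L) stop("required matches t must be >= 1")
  empty <- data.frame(chunk_id = integer(0), db_seq = integer(0),
                      db_seq_id = character(0), align_start = integer(0),
                      support = integer(0), stringsAsFactors = FALSE)
  if (nrow(keys) == 0L) return(empty)
  idx <- chunk$index
  hit_i <- findInterval(keys$code, idx$keys)
  hit_i[hit_i == 0L] <- NA_integer_
  ok <- which(!is.na(hit_i) & idx$keys[pmax(hit_i, 1L)] == keys$code)
  if (length(ok) == 0L) return(empty)
  hi <- hit_i[ok]
  counts <- idx$offsets[hi + 1L] - idx$offsets[hi]
  p <- idx$positions[sequence(counts, from = idx$offsets[hi] + 1L)]
  q <- rep(keys$offset[ok], counts)
  seqi <- findInterval(p, chunk$seq_table$start)
  # regions divide each database sequence, so predicted starts are
  # bucketed in sequence-relative coordinates: results are then invariant
  # to where the sequence lands in the concatenation (chunk invariance)
  d <- (p - chunk$seq_table$start[seqi]) - q
  b <- d %/% r
  out <- lapply(split(seq_along(d), seqi), function(ii) {
    bucket_candidates(d[ii], b[ii], t)
  })
  nseq <- as.integer(names(out))
  ncand <- vapply(out, nrow, 0L)
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) return(empty)
  db_seq <- rep(nseq, ncand)
  data.frame(chunk_id = chunk$chunk_id,
             db_seq = db_seq,
             db_seq_id = chunk$seq_table$seq_id[db_seq],
             align_start = chunk$seq_table$start[db_seq] + res$align_start,
             support = res$support,
             stringsAsFactors = FALSE)
}

# Emit candidates over region buckets for one database sequence.
# d: predicted starts; b: their buckets (floor(d / r)); t: threshold.
# One candidate per qualifying pair (b, b+1), anchored at the smallest
# contributing d; a pair whose supporting matches all lie in buckets
# already covered by an emitted pair is skipped (dedup), so no region is
# aligned twice yet none is lost.
bucket_candidates <- function(d, b, t) {
  ub <- sort(unique(b))
  cnt <- tabulate(match(b, ub))
  nxt <- match(ub + 1L, ub)             # index of right-adjacent bucket
  pairsum <- cnt + ifelse(is.na(nxt), 0L, cnt[pmax(nxt, 1L)])
  qb <- ub[pairsum >= t]
  if (length(qb) == 0L) {
    return(data.frame(align_start = integer(0), support = integer(0)))
  }
  covered <- integer(0)
  starts <- integer(0)
  supports <- integer(0)
  for (bb in qb) {
    sel <- b == bb | b == bb + 1L
    if (all(unique(b[sel]) %in% covered)) next
    starts <- c(starts, min(d[sel]))
    supports <- c(supports, sum(sel))
    covered <- c(covered, bb, bb + 1L)
  }
  data.frame(align_start = starts, support = supports)
}

#' Count candidates per query read
#'
#' Batching hook: returns, for each read, the total number of candidate
#' alignment positions across all six frames and all chunks, as used to
#' split query batches under a memory budget.
#'
#' @param reads Reads data frame (`id`, `bases`).
#' @param chunks List of `index_chunk` objects.
#' @param params A [search_params()].
#' @return Named integer vector of candidate counts, one per read.
#' @export
count_candidates <- function(reads, chunks, params = search_params()) {
  vapply(seq_len(nrow(reads)), function(i) {
    frames <- suppressWarnings(six_frame_translate(reads$bases[i]))
    total <- 0L
    for (tf in frames) {
      keys <- query_keys(tf, params$K, params$s)
      for (ch in chunks) {
        total <- total + nrow(find_candidates(keys, ch, params$r, params$t))
      }
    }
    total
  }, 0L, USE.NAMES = FALSE) |> setNames(reads$id)
}
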