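# Pipeline orchestration: translate -> query keys -> candidates -> window
# alignment, per query batch and per database chunk; merge, dedupe, sort,
# truncate, write.

#' Run configuration for a search
#'
#' @param params A [search_params()].
#' @param index_path Path to an index file from [save_chunks()].
#' @param query_path Path to a FASTQ or FASTA query file.
#' @param output_path Path for 12-column tabular output.
#' @param top_n Hits reported per read: the best `top_n`, plus ties within
#'   1 bit of the `top_n`-th.
#' @param batch_size Queries processed per batch (results are invariant to
#'   this; it only bounds memory).
#' @param min_bits Reporting threshold in bits (default 20).
#' @param apply_quality_filter Apply [quality_filter()] to FASTQ input.
#' @param lenient Map non-`{A,C,G,T,N}` bases to `N` instead of erroring.
#' @param seed RNG seed for sampling utilities (the search itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(params = search_params(), index_path = NULL,
                       query_path = NULL, output_path = NULL, top_n = 1L,
                       batch_size = 500L, min_bits = 20,
                       apply_quality_filter = FALSE, lenient = FALSE,
                       seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (top_n < 1L) stop("top_n must be >= 1")
  structure(list(params = params, index_path = index_path,
                 query_path = query_path, output_path = output_path,
                 top_n = as.integer(top_n),
                 batch_size = as.integer(batch_size),
                 min_bits = min_bits,
                 apply_quality_filter = apply_quality_filter,
                 lenient = lenient, seed = as.integer(seed)),
            class = "run_config")
}

#' Search reads against pre-built index chunks (in memory)
#'
#' The core engine behind [search_all()]: runs the full pipeline for a
#' reads data frame and returns the merged, deduplicated, sorted hits.
#' Results are independent of chunking and batching; per
#' `(read, frame, subject)` only the best-scoring alignment is kept, reads
#' are sorted by bit score descending with deterministic tie-breaking
#' (smallest subject id, subject start, then query start), and truncated
#' to `top_n` best hits per read plus ties within 1 bit.
#'
#' @param reads Reads data frame (`id`, `bases`).
#' @param chunks List of `index_chunk` objects.
#' @param params A [search_params()].
#' @param top_n Hits per read (plus near-ties, see above).
#' @param min_bits Reporting threshold in bits.
#' @param lenient Passed to the translator.
#' @return Hits data frame in internal (0-based) coordinates.
#' @export
search_reads <- function(reads, chunks, params = search_params(),
                         top_n = 1L, min_bits = 20, lenient = FALSE) {
  matrix <- resolve_matrix(params)
  min_raw <- raw_for_bits(min_bits)
  per_read <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    frames <- suppressWarnings(
      six_frame_translate(reads$bases[i], read_id = reads$id[i],
                          lenient = lenient))
    acc <- list()
    for (tf in frames) {
      keys <- query_keys(tf, params$K, params$s)
      if (nrow(keys) == 0L) next
      for (ch in chunks) {
        cands <- find_candidates(keys, ch, params$r, params$t)
        if (nrow(cands) == 0L) next
        acc[[length(acc) + 1L]] <-
          align_candidates(tf, cands, ch, params, min_raw, matrix)
      }
    }
    hits <- if (length(acc)) do.call(rbind, acc) else empty_hits()
    per_read[[i]] <- finalize_read_hits(hits, top_n)
  }
  out <- do.call(rbind, c(per_read, list(empty_hits())))
  rownames(out) <- NULL
  out
}

# dedupe per (frame, subject), sort, truncate for a single read
finalize_read_hits <- function(hits, top_n) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(-hits$raw_score, hits$subject_id, hits$s_start,
             hits$q_dna_start, hits$frame)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$frame, hits$subject_id)
  hits <- hits[!duplicated(key), , drop = FALSE]
  if (nrow(hits) > top_n) {
    cutoff <- hits$bit_score[top_n] - 1
    hits <- hits[hits$bit_score >= cutoff, , drop = FALSE]
  }
  hits
}

#' Run a full search from files
#'
#' Loads the index, reads queries (FASTA or FASTQ; FASTQ may be
#' quality-filtered first), searches every database chunk in batches,
#' merges per-read results across chunks, and writes 12-column tabular
#' output. Output is deterministic for fixed inputs and parameters and
#' invariant to chunking and batch size.
#'
#' @param config A [run_config()].
#' @return Invisibly, the hits data frame that was written.
#' @export
search_all <- function(config) {
  chunks <- load_chunks(config$index_path, config$params)
  queries <- read_queries(config$query_path)
  if (config$apply_quality_filter && !is.null(queries$quals)) {
    queries <- quality_filter(queries)
  }
  n <- nrow(queries)
  out <- vector("list", 0L)
  for (lo in seq.int(1L, max(n, 1L), by = config$batch_size)) {
    if (n == 0L) break
    batch <- queries[lo:min(lo + config$batch_size - 1L, n), , drop = FALSE]
    out[[length(out) + 1L]] <-
      search_reads(batch, chunks, config$params, config$top_n,
                   config$min_bits, config$lenient)
  }
  hits <- do.call(rbind, c(out, list(empty_hits())))
  rownames(hits) <- NULL
  if (!is.null(config$output_path)) write_tabular(hits, config$output_path)
  invisible(hits)
}

# FASTQ if the first content line starts with '@', else FASTA of DNA reads
read_queries <- function(path) {
  first <- first_content_line(path)
  if (is.null(first)) return(new_reads(character(0), character(0), list()))
  if (startsWith(first$text, "@")) return(read_fastq(path))
  if (!startsWith(first$text, ">")) {
    stop("query file is neither FASTA nor FASTQ: ", path)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  df <- data.frame(id = sub("\\s.*$", "", names(set)),
                   bases = toupper(unname(as.character(set))),
                   stringsAsFactors = FALSE)
  df$quals <- rep(list(NULL), nrow(df))
  df
}

#' Best hits per read from a hits data frame
#'
#' Convenience accessor: the top-scoring hit rows (rank-1 ties included)
#' for each read.
#'
#' @param hits Hits data frame from [search_reads()].
#' @return Hits data frame restricted to each read's maximal bit score.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  best <- tapply(hits$raw_score, hits$read_id, max)
  hits[hits$raw_score == best[hits$read_id], , drop = FALSE]
}
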