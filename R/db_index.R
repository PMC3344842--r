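# Chunked k-mer inverted index over the protein database. Sequences are
# concatenated with a delimiter sentinel; keys are generated at every
# offset whose K-mer lies inside one sequence and contains only the 20
# amino acids (keys containing X or * are uninformative and excluded).

#' Greedy chunk assignment from sequence lengths
#'
#' Sequences are packed into chunks in input order; a new chunk starts when
#' adding the next sequence would exceed `chunk_limit` residues. This is
#' the minimal chunk count achievable without reordering.
#'
#' @param lengths Integer/numeric vector of sequence lengths (residues).
#' @param chunk_limit Maximum residues per chunk.
#' @return Integer vector of 1-based chunk ids, one per sequence.
#' @export
plan_chunks <- function(lengths, chunk_limit) {
  if (any(lengths > chunk_limit)) {
    stop("a sequence of length ", max(lengths), " exceeds the chunk limit ",
         chunk_limit, "; increase the limit")
  }
  n <- length(lengths)
  ids <- integer(n)
  cur <- 1L
  used <- 0
  for (i in seq_len(n)) {
    if (used + lengths[i] > chunk_limit && used > 0) {
      cur <- cur + 1L
      used <- 0
    }
    used <- used + lengths[i]
    ids[i] <- cur
  }
  ids
}

#' Build chunked k-mer indexes over a protein database
#'
#' @param db Data frame of protein records (`id`, `residues`), e.g. from
#'   [read_fasta()].
#' @param params A [search_params()] object (uses `K` and `chunk_limit`).
#' @return A list of `index_chunk` objects.
#' @export
build_chunks <- function(db, params = search_params()) {
  if (nrow(db) == 0L) return(list())
  lens <- nchar(db$residues)
  assign <- plan_chunks(lens, params$chunk_limit)
  lapply(unique(assign), function(cid) {
    rows <- which(assign == cid)
    make_chunk(cid, db$id[rows], db$residues[rows], params$K)
  })
}

make_chunk <- function(chunk_id, ids, residues, K) {
  codes <- lapply(residues, encode_residues)
  lens <- lengths(codes)
  n <- length(codes)
  # interleave delimiter codes between sequences
  pieces <- vector("list", 2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- codes
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- list(GS_DELIM)
  concat <- unlist(pieces, use.names = FALSE)
  start <- cumsum(c(0L, head(lens + 1L, -1L)))  # 0-based starts in concat
  structure(list(chunk_id = chunk_id,
                 concat = concat,
                 seq_table = data.frame(seq_id = ids, start = start,
                                        length = lens,
                                        stringsAsFactors = FALSE),
                 index = index_positions(concat, K),
                 K = as.integer(K)),
            class = "index_chunk")
}

#' @export
print.index_chunk <- function(x, ...) {
  cat(sprintf("index_chunk %d: %d sequences, %d residues, K=%d, %d keys\n",
              x$chunk_id, nrow(x$seq_table),
              sum(x$seq_table$length), x$K, length(x$index$keys)))
  invisible(x)
}

# Rolling base-23 k-mer codes over a code vector; offsets whose window
# contains a code outside the 20 amino acids are invalid (NA).
kmer_codes <- function(codes, K) {
  n <- length(codes)
  if (n < K) return(integer(0))
  noff <- n - K + 1L
  val <- numeric(noff)
  bad <- codes > 20L
  nbad <- 0L
  if (any(bad)) {
    cb <- cumsum(bad)
    nbad <- cb[K:n] - c(0L, cb)[1:noff]
  }
  for (i in seq_len(K)) {
    val <- val * 23 + (codes[i:(i + noff - 1L)] - 1L)
  }
  val <- as.integer(val)
  if (length(nbad) > 1L || any(nbad > 0L)) val[nbad > 0L] <- NA_integer_
  val
}

# Inverted index: sorted unique key codes, per-key slice boundaries, and
# positions (0-based, ascending within each key: order of appearance).
index_positions <- function(concat, K) {
  kc <- kmer_codes(concat, K)
  pos <- which(!is.na(kc))
  codes <- kc[pos]
  o <- order(codes, pos)
  codes <- codes[o]
  pos <- pos[o] - 1L  # 0-based
  keys <- unique(codes)
  counts <- tabulate(match(codes, keys))
  list(keys = keys, offsets = c(0L, cumsum(counts)), positions = pos)
}

key_to_code <- function(key) {
  codes <- encode_residues(key)
  if (any(codes > 20L)) return(NA_integer_)
  v <- 0
  for (c in codes) v <- v * 23 + (c - 1L)
  as.integer(v)
}

lookup_code <- function(index, code) {
  if (is.na(code) || length(index$keys) == 0L) return(integer(0))
  i <- findInterval(code, index$keys)
  if (i == 0L || index$keys[i] != code) return(integer(0))
  index$positions[(index$offsets[i] + 1L):index$offsets[i + 1L]]
}

#' Look up a k-mer key in a chunk index
#'
#' @param chunk An `index_chunk`.
#' @param key A residue string of length `K`.
#' @return Ascending 0-based positions in the chunk's concatenated
#'   residues at which the key occurs; empty if absent or if the key
#'   contains a character outside the 20 amino acids.
#' @export
lookup <- function(chunk, key) {
  if (nchar(key) != chunk$K) {
    stop("key length ", nchar(key), " does not match index K=", chunk$K)
  }
  lookup_code(chunk$index, key_to_code(key))
}

#' Save / load a chunked index
#'
#' The container is versioned and self-describing (stores `K` and
#' `chunk_limit`); loading verifies the format and, when search parameters
#' are supplied, that the index was built with the same seed length.
#'
#' @param chunks List of `index_chunk` objects from [build_chunks()].
#' @param path File path.
#' @param params Optional [search_params()]; `K` and `chunk_limit` are
#'   recorded in the header.
#' @return `save_chunks`: invisibly, `path`. `load_chunks`: the chunk list,
#'   with the header attached as attribute `header`.
#' @export
save_chunks <- function(chunks, path, params = search_params()) {
  obj <- list(format = "ghostseek-index", version = 1L,
              K = if (length(chunks)) chunks[[1L]]$K else params$K,
              chunk_limit = params$chunk_limit,
              n_chunks = length(chunks),
              chunks = chunks)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_chunks
#' @export
load_chunks <- function(path, params = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read index file '", path, "': ", conditionMessage(e),
         " (truncated or not an index?)")
  })
  if (!is.list(obj) || !identical(obj$format, "ghostseek-index")) {
    stop("not a ghostseek index file: ", path)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported index format version: ", obj$version)
  }
  if (!is.null(params) && params$K != obj$K) {
    stop(errorCondition(
      paste0("index was built with K=", obj$K, " but search requested K=",
             params$K, "; rebuild the index or adjust -k"),
      class = "gs_k_mismatch"))
  }
  structure(obj$chunks, header = obj[c("version", "K", "chunk_limit",
                                       "n_chunks")])
}
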