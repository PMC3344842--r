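# Internal residue alphabet: the 20 amino acids (NCBI matrix order),
# 'X' (any), '*' (stop), and '|' (database delimiter sentinel).
GS_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GS_ALPHABET <- c(GS_AA, "X", "*", "|")
GS_X <- 21L
GS_STOP <- 22L
GS_DELIM <- 23L

# fast char -> code lookup indexed by ASCII byte; unknowns map to X
gs_code_table <- function() {
  if (is.null(.gs$code_table)) {
    tab <- rep(GS_X, 127L)
    tab[vapply(GS_ALPHABET, utf8ToInt, 0)] <- seq_along(GS_ALPHABET)
    .gs$code_table <- as.integer(tab)
  }
  .gs$code_table
}

#' Encode a residue string as integer codes
#'
#' Maps each character of a protein string onto the internal 23-letter
#' alphabet (20 amino acids, `X`, `*`, and the `|` delimiter sentinel).
#' Characters outside the alphabet become `X`.
#'
#' @param x A single protein string (uppercase).
#' @return Integer vector of 1-based codes into the internal alphabet `GS_ALPHABET`.
#' @keywords internal
encode_residues <- function(x) {
  if (nchar(x) == 0L) return(integer(0))
  gs_code_table()[utf8ToInt(x)]
}

decode_residues <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(GS_ALPHABET[codes], collapse = "")
}

#' Search parameters
#'
#' Collects every tunable of the search pipeline. Defaults correspond to
#' the tool's reference configuration: seed length K=4, query-key skip
#' s=2, region size r=4, window extension e=2, required seed matches t=2,
#' database chunks of at most 128 million residues, and BLOSUM62 with
#' affine gap penalties 11 (open) / 1 (extend).
#'
#' @param K Seed (k-mer) length in residues. Must be between 1 and 6.
#' @param s Skip between successive query key offsets, in residues.
#' @param r Region size used to bucket predicted alignment starts, residues.
#' @param e Extension added on each side of the alignment window, residues.
#' @param t Minimum number of seed matches in a region plus its right
#'   neighbour for a candidate to be emitted.
#' @param chunk_limit Maximum number of residues per database chunk.
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty (positive); a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param matrix Substitution matrix name; only "BLOSUM62" is bundled.
#' @return An object of class `search_params`.
#' @export
#' @examples
#' search_params()           # reference defaults
#' search_params(K = 3, s = 1, t = 1)  # high-sensitivity setting
search_params <- function(K = 4L, s = 2L, r = 4L, e = 2L, t = 2L,
                          chunk_limit = 128e6, gap_open = 11L,
                          gap_extend = 1L, matrix = "BLOSUM62") {
  K <- as.integer(K); s <- as.integer(s); r <- as.integer(r)
  e <- as.integer(e); t <- as.integer(t)
  if (is.na(K) || K < 1L || K > 6L) stop("K must be in 1..6")
  if (is.na(s) || s < 1L) stop("s must be >= 1")
  if (is.na(r) || r < 1L) stop("r must be >= 1")
  if (is.na(e) || e < 0L) stop("e must be >= 0")
  if (is.na(t) || t < 1L) stop("t must be >= 1")
  if (!is.numeric(chunk_limit) || chunk_limit < 1) {
    stop("chunk_limit must be a positive number of residues")
  }
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  structure(list(K = K, s = s, r = r, e = e, t = t,
                 chunk_limit = as.numeric(chunk_limit),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 matrix = matrix),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf(
    "search_params: K=%d s=%d r=%d e=%d t=%d chunk_limit=%g gaps=%d/%d %s\n",
    x$K, x$s, x$r, x$e, x$t, x$chunk_limit, x$gap_open, x$gap_extend,
    x$matrix))
  invisible(x)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix format used by NCBI BLAST
#' (comment lines starting with `#`, a header row of residue labels, then
#' one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return A square integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path)
  labels <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- length(labels)
  m <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1L]]
    if (fields[[1L]] != labels[[i]] || length(fields) != n + 1L) {
      stop("malformed matrix row ", i, " in ", path)
    }
    m[i, ] <- as.integer(fields[-1L])
  }
  m
}

#' The bundled BLOSUM62 matrix on the internal alphabet
#'
#' Returns BLOSUM62 expanded to the internal 23-letter alphabet. `X` scores
#' are taken from the matrix file; the stop symbol `*` is assigned the
#' matrix minimum against every residue (and itself) so that alignments are
#' penalised for crossing a stop codon; the delimiter row is strongly
#' negative and never participates in scoring.
#'
#' @return A 23 x 23 integer matrix with internal-alphabet dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.gs$blosum62)) {
    raw <- read_score_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "ghostseek",
                  mustWork = TRUE))
    .gs$blosum62 <- expand_matrix(raw)
  }
  .gs$blosum62
}

# Expand an NCBI matrix (20 aa + possibly B/Z/X/*) onto GS_ALPHABET.
expand_matrix <- function(raw) {
  core <- c(GS_AA, "X")
  if (!all(core %in% rownames(raw))) {
    stop("matrix must cover the 20 amino acids and X")
  }
  m <- matrix(-10000L, 23L, 23L, dimnames = list(GS_ALPHABET, GS_ALPHABET))
  m[core, core] <- raw[core, core]
  worst <- min(raw[GS_AA, GS_AA])
  m["*", c(core, "*")] <- worst
  m[c(core, "*"), "*"] <- worst
  storage.mode(m) <- "integer"
  m
}

# Resolve a params$matrix name to the expanded internal matrix.
resolve_matrix <- function(params) {
  if (identical(params$matrix, "BLOSUM62")) return(blosum62())
  if (file.exists(params$matrix)) return(expand_matrix(read_score_matrix(params$matrix)))
  stop("unknown substitution matrix: ", params$matrix)
}
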