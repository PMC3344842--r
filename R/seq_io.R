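# Sequence I/O: FASTA / FASTQ parsing (via Biostrings), the read-quality
# filter, and 12-column BLAST tabular output.

#' Read a protein FASTA file
#'
#' Record ids are truncated at the first whitespace; residues are
#' uppercased and any character outside the 20 amino acids plus `X` is
#' mapped to `X` at parse time.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data frame with columns `id` and `residues`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- first_content_line(path)
  if (!is.null(first) && !startsWith(first$text, ">")) {
    stop("FASTA parse error at line ", first$n,
         ": sequence data before any '>' header")
  }
  if (is.null(first)) {
    return(data.frame(id = character(0), residues = character(0),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  res <- toupper(as.character(set))
  res <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", res)
  if (any(!nzchar(res))) {
    stop("empty sequence for record: ", ids[!nzchar(res)][1L])
  }
  data.frame(id = ids, residues = unname(res), stringsAsFactors = FALSE)
}

first_content_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return(NULL)
    n <- n + 1L
    if (nzchar(trimws(line))) return(list(text = trimws(line), n = n))
  }
}

#' Read a FASTQ file of DNA reads
#'
#' Expects 4-line records with Phred+33 quality strings. Bases are
#' uppercased; qualities are decoded to integer Phred scores.
#'
#' @param path Path to a FASTQ file.
#' @return A data frame with columns `id`, `bases`, and a list-column
#'   `quals` of integer Phred scores (one vector per read).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks
  if (length(lines) == 0L) {
    return(new_reads(character(0), character(0), list()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error: truncated record (", length(lines),
         " lines is not a multiple of 4)")
  }
  i <- seq(1L, length(lines), by = 4L)
  heads <- lines[i]
  bases <- toupper(lines[i + 1L])
  plus <- lines[i + 2L]
  qstr <- lines[i + 3L]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ parse error at record ", bad[1L],
         ": expected '@' header and '+' separator")
  }
  mism <- which(nchar(bases) != nchar(qstr))
  if (length(mism)) {
    stop("FASTQ parse error at record ", mism[1L],
         ": sequence and quality lengths differ")
  }
  ids <- sub("\\s.*$", "", substring(heads, 2L))
  quals <- lapply(qstr, function(q) utf8ToInt(q) - 33L)
  new_reads(ids, bases, quals)
}

new_reads <- function(ids, bases, quals) {
  df <- data.frame(id = ids, bases = bases, stringsAsFactors = FALSE)
  df$quals <- quals
  df
}

#' Filter reads on a sustained stretch of base quality
#'
#' Keeps a read only if it carries a contiguous run of bases with Phred
#' quality at least `q_min` that is at least `min_run` bases long. With
#' `trim = TRUE` (default) the read is trimmed to its longest qualifying
#' run; with `trim = FALSE` reads are kept whole (pass/fail only).
#'
#' @param reads A reads data frame from [read_fastq()].
#' @param q_min Minimum per-base Phred quality (default 15).
#' @param min_run Minimum run length in bases (default 60).
#' @param trim Trim to the longest qualifying run, or keep whole reads.
#' @return The filtered (and possibly trimmed) reads data frame; zero rows
#'   if no read qualifies.
#' @export
quality_filter <- function(reads, q_min = 15L, min_run = 60L, trim = TRUE) {
  if (is.null(reads$quals)) {
    stop("reads carry no quality scores; use the FASTA path (no filtering)")
  }
  runs <- lapply(reads$quals, function(q) {
    if (is.null(q)) stop(
      "read without qualities; use the FASTA path (no filtering)")
    longest_run(q >= q_min)
  })
  len <- vapply(runs, `[[`, 0L, "len")
  keep <- len >= min_run
  out <- reads[keep, , drop = FALSE]
  if (trim && nrow(out)) {
    st <- vapply(runs[keep], `[[`, 0L, "start")
    ln <- len[keep]
    out$bases <- substring(out$bases, st, st + ln - 1L)
    out$quals <- Map(function(q, s, l) q[s:(s + l - 1L)], out$quals, st, ln)
  }
  rownames(out) <- NULL
  out
}

# longest TRUE run; first one wins on ties. Returns 1-based start + length.
longest_run <- function(ok) {
  if (!any(ok)) return(list(start = 1L, len = 0L))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  j <- i[which.max(r$lengths[i])]
  list(start = starts[j], len = r$lengths[j])
}

#' Write hits in 12-column BLAST tabular format
#'
#' Emits the classic `blast8` / `-outfmt 6` columns: query id, subject id,
#' percent identity, alignment length, mismatches, gap openings, query
#' start/end, subject start/end, e-value, bit score. Coordinates are
#' converted here from the internal 0-based half-open convention to
#' 1-based inclusive; query coordinates are DNA positions on the original
#' read, with `qstart > qend` for negative-frame hits. The e-value column
#' holds the placeholder -1 unless hits carry a precomputed `evalue`.
#'
#' @param hits A hits data frame as produced by the search pipeline.
#' @param path Output file path (or connection).
#' @return Invisibly, the data frame that was written.
#' @export
write_tabular <- function(hits, path) {
  tab <- hits_to_tabular(hits)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(tab)
}

hits_to_tabular <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = character(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = character(0), bitscore = character(0),
                      stringsAsFactors = FALSE))
  }
  neg <- hits$frame < 0L
  qstart <- ifelse(neg, hits$q_dna_end, hits$q_dna_start + 1L)
  qend <- ifelse(neg, hits$q_dna_start + 1L, hits$q_dna_end)
  ev <- if (!is.null(hits$evalue)) formatC(hits$evalue, format = "g", digits = 3) else "-1"
  data.frame(
    qseqid = hits$read_id,
    sseqid = hits$subject_id,
    pident = sprintf("%.2f", hits$identity_pct),
    length = hits$align_len,
    mismatch = hits$mismatches,
    gapopen = hits$gap_openings,
    qstart = as.integer(qstart),
    qend = as.integer(qend),
    sstart = hits$s_start + 1L,
    send = hits$s_end,
    evalue = ev,
    bitscore = sprintf("%.1f", hits$bit_score),
    stringsAsFactors = FALSE)
}

#' Read a 12-column BLAST tabular file
#'
#' @param path Path to a tab-separated 12-column hits file.
#' @return A data frame with the standard blast8 column names.
#' @export
read_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12L), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  out <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "integer", "integer",
                                   "integer", "integer", "integer",
                                   "integer", "character", "numeric"),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

#' Write protein records as FASTA
#' @param db Data frame with `id` and `residues` columns.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(db, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    writeLines(paste0(">", db$id[i]), con)
    s <- db$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write DNA reads as FASTQ (Phred+33)
#' @param reads Reads data frame (`id`, `bases`, list-column `quals`).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qstr <- vapply(reads$quals, function(q) intToUtf8(q + 33L), "")
  lines <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", qstr))
  writeLines(lines, path)
  invisible(path)
}
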