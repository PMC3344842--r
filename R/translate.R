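# Six-frame translation of DNA reads with the N -> X ambiguity rule, and
# back-mapping of protein intervals onto forward-strand DNA coordinates.

gs_codon_table <- function() {
  if (is.null(.gs$codons)) {
    .gs$codons <- Biostrings::GENETIC_CODE  # standard code, DNA-style names
  }
  .gs$codons
}

#' Reverse complement of a DNA string
#' @param bases DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement string.
#' @export
revcomp <- function(bases) {
  if (nchar(bases) == 0L) return(bases)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", bases))))
}

frame_offset <- function(frame) abs(frame) - 1L

#' Translate one reading frame of a DNA string
#'
#' Frames `+1,+2,+3` read the forward strand starting at offsets 0,1,2;
#' frames `-1,-2,-3` read the reverse complement likewise. Any codon
#' containing `N` translates to `X`; stop codons translate to `*`.
#'
#' @param bases DNA string over `{A,C,G,T,N}`.
#' @param frame One of `+1,+2,+3,-1,-2,-3`.
#' @param lenient If `TRUE`, IUPAC ambiguity characters other than `N` are
#'   mapped to `N` (hence `X` in the protein); if `FALSE` (default) such
#'   characters are rejected with an error naming the offender.
#' @return A `translated_frame` list with `frame`, `residues`, `dna_length`.
#' @export
#' @examples
#' translate_frame("ATGAAA", 1L)$residues   # "MK"
#' translate_frame("TTTCAT", -1L)$residues  # "MK"
translate_frame <- function(bases, frame, lenient = FALSE) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  bases <- toupper(bases)
  bad <- regmatches(bases, regexpr("[^ACGTN]", bases))
  if (length(bad) && nzchar(bad)) {
    if (!lenient) stop("invalid DNA character '", bad, "' (use lenient mode ",
                       "to map IUPAC ambiguity codes to N)")
    bases <- gsub("[^ACGTN]", "N", bases)
  }
  n <- nchar(bases)
  s <- if (frame < 0L) revcomp(bases) else bases
  off <- frame_offset(frame)
  ncod <- max(0L, (n - off) %/% 3L)
  residues <- if (ncod == 0L) "" else {
    starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
    aa <- unname(gs_codon_table()[substring(s, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"  # any codon containing N
    paste(aa, collapse = "")
  }
  structure(list(frame = as.integer(frame), residues = residues,
                 dna_length = n),
            class = "translated_frame")
}

#' Translate a read in all six reading frames
#'
#' @param bases DNA string of length at least 3 (shorter input yields an
#'   empty list with a warning).
#' @param read_id Optional read identifier attached to each frame.
#' @inheritParams translate_frame
#' @return A list of six `translated_frame` objects in the order
#'   `+1,+2,+3,-1,-2,-3`.
#' @export
six_frame_translate <- function(bases, read_id = NULL, lenient = FALSE) {
  if (nchar(bases) < 3L) {
    warning("read shorter than 3 bases cannot be translated")
    return(list())
  }
  frames <- lapply(c(1L, 2L, 3L, -1L, -2L, -3L), function(f) {
    tf <- translate_frame(bases, f, lenient = lenient)
    tf$read_id <- read_id
    tf
  })
  frames
}

#' Map a protein interval of a frame back to DNA coordinates
#'
#' Returns the 0-based half-open interval on the forward strand of the
#' original read covering the codons of `protein_len` residues starting at
#' `protein_start` (0-based) in the given frame. Orientation is carried by
#' the frame sign, not by the interval.
#'
#' @param frame Frame tag in `+1..+3, -1..-3`.
#' @param protein_start 0-based start residue within the frame.
#' @param protein_len Number of residues.
#' @param dna_length Length of the read in bases.
#' @return Integer vector `c(dna_start, dna_end)`, 0-based half-open.
#' @export
back_map <- function(frame, protein_start, protein_len, dna_length) {
  off <- frame_offset(frame)
  nres <- (dna_length - off) %/% 3L
  if (protein_start < 0L || protein_len < 0L ||
      protein_start + protein_len > nres) {
    stop("protein interval [", protein_start, ", ",
         protein_start + protein_len, ") outside frame bounds (", nres,
         " residues)")
  }
  a <- off + 3L * protein_start
  b <- a + 3L * protein_len
  if (frame > 0L) c(a, b) else c(dna_length - b, dna_length - a)
}
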