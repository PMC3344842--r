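# Synthetic protein database and read simulator. Database residues are
# drawn i.i.d. from the BLOSUM62 background amino-acid frequencies; reads
# are reverse-translated from database fragments after introducing
# substitutions (BLOSUM62-conditional) and rare indels, on either strand.

# BLOSUM62 background amino-acid frequencies (Henikoff marginals), in
# GS_AA (NCBI matrix) order. They sum to 1.
GS_BG_FREQ <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073)

# ungapped BLOSUM62 lambda, used for the conditional substitution model
GS_LAMBDA_UNGAPPED <- 0.3176

#' Specification of a synthetic database/read fixture
#'
#' @param n_db_seqs Number of database protein sequences.
#' @param db_len_range Length range of database sequences (residues).
#' @param n_reads Number of DNA reads to simulate.
#' @param read_len_range Read length range in bases (default 60-75).
#' @param target_identity Amino-acid identity of the encoded fragment with
#'   its source; a single fraction or a `c(lo, hi)` range sampled
#'   per read.
#' @param indel_rate Per-residue probability of a 1-residue indel.
#' @param quality_profile Function `n -> integer Phred scores` used for
#'   FASTQ emission.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_db_seqs = 2000L, db_len_range = c(100L, 500L),
                           n_reads = 2000L, read_len_range = c(60L, 75L),
                           target_identity = c(0.6, 0.9),
                           indel_rate = 0.005,
                           quality_profile = default_quality_profile,
                           seed = 1L) {
  if (any(target_identity <= 0) || any(target_identity > 1)) {
    stop("target_identity must lie in (0, 1]")
  }
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0, 1)")
  structure(list(n_db_seqs = as.integer(n_db_seqs),
                 db_len_range = as.integer(db_len_range),
                 n_reads = as.integer(n_reads),
                 read_len_range = as.integer(read_len_range),
                 target_identity = target_identity,
                 indel_rate = indel_rate,
                 quality_profile = quality_profile,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default Phred quality profile (truncated normal around Q35)
#' @param n Number of bases.
#' @return Integer Phred scores.
#' @export
default_quality_profile <- function(n) {
  pmin(40L, pmax(2L, as.integer(round(rnorm(n, mean = 35, sd = 3)))))
}

#' Generate a synthetic protein database
#'
#' Residues are i.i.d. from the BLOSUM62 background frequencies; lengths
#' are uniform over `db_len_range`. Deterministic for a fixed spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Protein records data frame (`id`, `residues`).
#' @export
generate_db <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_db_seqs
  if (n == 0L) {
    return(data.frame(id = character(0), residues = character(0),
                      stringsAsFactors = FALSE))
  }
  lens <- sample.int(spec$db_len_range[2L] - spec$db_len_range[1L] + 1L, n,
                     replace = TRUE) + spec$db_len_range[1L] - 1L
  aa <- sample(GS_AA, sum(lens), replace = TRUE, prob = GS_BG_FREQ)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  data.frame(id = sprintf("dbseq%05d", seq_len(n)),
             residues = vapply(seq_len(n), function(i) {
               paste(aa[starts[i]:ends[i]], collapse = "")
             }, ""),
             stringsAsFactors = FALSE)
}

# 20x20 conditional substitution matrix: P(b | a) with b != a,
# proportional to p_b * exp(lambda_u * s(a, b)).
substitution_conditional <- function() {
  if (!is.null(.gs$subst_cond)) return(.gs$subst_cond)
  s <- blosum62()[GS_AA, GS_AA]
  w <- sweep(exp(GS_LAMBDA_UNGAPPED * s), 2L, GS_BG_FREQ, `*`)
  diag(w) <- 0
  .gs$subst_cond <- sweep(w, 1L, rowSums(w), `/`)
  .gs$subst_cond
}

# codon choices per amino acid (standard code); stop codons excluded
codon_choices <- function() {
  if (is.null(.gs$codon_choices)) {
    gc <- gs_codon_table()
    .gs$codon_choices <- split(names(gc), gc)
  }
  .gs$codon_choices
}

#' Simulate DNA reads from a protein database
#'
#' Each read takes a random fragment of a random database sequence,
#' substitutes residues to reach its target identity (substitutions drawn
#' from BLOSUM62 conditional probabilities), applies rare 1-residue
#' indels, reverse-translates with uniformly random synonymous codons,
#' trims to the drawn read length, places the read on a random strand, and
#' attaches Phred qualities from the quality profile.
#'
#' @param db Protein records data frame from [generate_db()].
#' @param spec A [synthetic_spec()].
#' @return A list with `reads` (data frame `id`, `bases`, `quals`) and
#'   `truth` (data frame `read_id`, `subject_id`, `frame`,
#'   `subject_start`, `subject_end` (1-based inclusive),
#'   `realized_identity`).
#' @export
generate_reads <- function(db, spec) {
  if (nrow(db) == 0L) stop("database is empty")
  set.seed(spec$seed + 1L)
  cond <- substitution_conditional()
  codons <- codon_choices()
  n <- spec$n_reads
  ids <- sprintf("read%05d", seq_len(n))
  bases <- character(n)
  quals <- vector("list", n)
  truth <- data.frame(read_id = ids, subject_id = character(n),
                      frame = integer(n), subject_start = integer(n),
                      subject_end = integer(n),
                      realized_identity = numeric(n),
                      stringsAsFactors = FALSE)
  id_rng <- spec$target_identity
  if (length(id_rng) == 1L) id_rng <- c(id_rng, id_rng)
  db_lens <- nchar(db$residues)
  for (i in seq_len(n)) {
    L_read <- sample.int(spec$read_len_range[2L] - spec$read_len_range[1L] +
                           1L, 1L) + spec$read_len_range[1L] - 1L
    L_aa <- as.integer(ceiling(L_read / 3))
    repeat {
      n_indel <- rbinom(1L, L_aa, spec$indel_rate)
      ins <- if (n_indel) sum(runif(n_indel) < 0.5) else 0L
      del <- n_indel - ins
      S <- L_aa - ins + del          # residues taken from the source
      src <- sample.int(nrow(db), 1L)
      if (db_lens[src] >= S && S >= 1L) break
    }
    start <- sample.int(db_lens[src] - S + 1L, 1L)
    frag <- strsplit(substring(db$residues[src], start,
                               start + S - 1L), "")[[1L]]
    tid <- runif(1L, id_rng[1L], id_rng[2L])
    n_sub <- min(S, round((1 - tid) * S))
    if (n_sub > 0L) {
      at <- sample.int(S, n_sub)
      frag[at] <- vapply(frag[at], function(a) {
        sample(GS_AA, 1L, prob = cond[a, ])
      }, "")
    }
    if (del > 0L) frag <- frag[-sample.int(length(frag), del)]
    if (ins > 0L) {
      for (k in seq_len(ins)) {
        at <- sample.int(length(frag) + 1L, 1L)
        frag <- append(frag, sample(GS_AA, 1L, prob = GS_BG_FREQ), at - 1L)
      }
    }
    dna <- paste(vapply(frag, function(a) {
      ch <- codons[[a]]
      ch[[sample.int(length(ch), 1L)]]
    }, ""), collapse = "")
    dna <- substring(dna, 1L, L_read)
    fwd <- runif(1L) < 0.5
    bases[i] <- if (fwd) dna else revcomp(dna)
    quals[[i]] <- spec$quality_profile(L_read)
    truth$subject_id[i] <- db$id[src]
    truth$frame[i] <- if (fwd) 1L else -1L
    truth$subject_start[i] <- start
    truth$subject_end[i] <- start + S - 1L
    truth$realized_identity[i] <- (S - n_sub) / S
  }
  list(reads = new_reads(ids, bases, quals), truth = truth)
}
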