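---
title: "Seeded translated search: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded translated search: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metagenomic sequencing yields large numbers of short DNA reads (here,
60–75 bp) from organisms that rarely have a close reference genome.
Protein-level search tolerates far more divergence than nucleotide
comparison, so the standard move is a translated search: translate every
read in all six reading frames and look for local alignments against a
protein database, as BLASTX does. Exhaustive Smith–Waterman over every
(frame, subject) pair is the sensitivity gold standard but is far too slow
at survey scale. ghostseek implements a seed-and-extend approximation of
that search and ships the exhaustive search alongside it, so the
approximation error can always be measured rather than assumed.

## The search model

**Index.** Database sequences are concatenated with a delimiter sentinel
and every K-mer offset that lies inside a single sequence and contains
only the 20 amino acids is recorded in an inverted index (position lists
kept in order of appearance). Keys containing `X` would match anything in
scoring but are uninformative as exact keys, so they are not indexed.
Databases larger than `chunk_limit` residues are split greedily, in input
order, into chunks that are searched independently and merged, so peak
memory is bounded by the chunk size and results are provably independent
of the chunking.

**Candidates.** Each translated frame contributes query keys at offsets
`0, s, 2s, …`; keys containing `X` or `*` are skipped. A key match at
database position `p` for query offset `q` predicts an alignment start
`d = p − q`. Each database sequence is divided into regions of width `r`
over these predicted starts, and whenever a region plus its right
neighbour holds at least `t` matches, a candidate anchored at the
smallest contributing `d` is emitted. A region pair whose matches are
wholly covered by an already-emitted pair is skipped, so a database
stretch is aligned once. Two details here are deliberate design choices
where the procedure was underdetermined:

* Regions are laid over *sequence-relative* predicted starts. Bucketing
  the concatenated coordinate instead would make region boundaries — and
  therefore candidate sets — depend on where a sequence happens to land
  in a chunk, breaking chunk invariance.
* Overlapping qualifying region pairs are deduplicated by the
  "wholly-contained pair" rule rather than merged into one run-wide
  candidate. Merging would anchor the fixed-size alignment window at the
  run's leftmost predicted start, which can push the window off
  alignments near the run's right edge; pair-wise emission keeps every
  qualifying pair's window and is what makes sensitivity monotone in
  `K`, `s`, and `t` in practice.

**Alignment.** Each candidate is scored by Smith–Waterman with affine
gaps, restricted to a database window of size `m + 2r + 2e` around the
predicted start (`m` = frame length in residues): `r` absorbs the
within-region uncertainty of the anchor and `e` absorbs gap drift. The
window is clipped at the candidate's sequence boundaries and never
crosses a delimiter. Raw scores are converted to bit scores with the
standard Karlin–Altschul form `(λS − ln k)/ln 2`.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `K` | seed length, residues | 4 | smaller K = more sensitive, slower |
| `s` | query key skip, residues | 2 | `s = 1` samples every offset |
| `r` | region width, residues | 4 | recall is nearly flat in 2–8 |
| `e` | window extension, residues | 2 | nearly flat in 0–4 |
| `t` | required matches per region pair | 2 | `t = 1` = any single seed |
| `chunk_limit` | residues per chunk | 128×10⁶ | memory bound only |
| `gap_open`, `gap_extend` | affine gap costs | 11, 1 | a gap of length L costs 11 + L |
| λ, k | bit-score constants | 0.267, 0.041 | gapped BLOSUM62 11/1 convention |

The reporting threshold defaults to 20 bits (raw ≈ 40); hits below ~50
bits are conventionally regarded as attainable by chance and the
sensitivity evaluation conditions on the oracle's ≥ 50-bit hits.

## Numerical and edge-case choices

* **Stop codons** translate to `*`, which scores the matrix minimum (−4
  for BLOSUM62) against everything, including itself — the NCBI file's
  `*`/`*` entry of +1 is overridden so stop-rich frames cannot
  accumulate score. Seeds never contain `*`, so frames are effectively
  broken at stops for seeding but keep their coordinates.
* **Ambiguity.** Any codon containing `N` translates to `X` (scored from
  the matrix's X column). Other IUPAC codes are rejected by default; a
  lenient flag maps them to `N` first.
* **The e-value column** of the 12-column tabular output holds the
  placeholder −1: e-values depend on database-size statistics the search
  itself does not fix, while bit scores are database-independent.
* **Tie-breaking** is fully deterministic: equal-scoring alignments
  prefer the smallest subject coordinate, then query coordinate; per
  (read, frame, subject) only the best alignment is kept; reads report
  their `top_n` best hits plus ties within 1 bit.
* **Coordinates** are 0-based half-open internally; conversion to
  1-based inclusive (with `qstart > qend` on negative frames) happens
  only when writing tabular output.
* **Quality filter.** Reads are kept when they have a run of ≥ 60 bases
  at Phred ≥ 15, and by default are trimmed to the longest such run;
  "greater than 15 (Q15 or over)" is read as ≥ 15 and "more than 60 bp"
  as ≥ 60, consistent with retained read lengths of 60–75 bp. A
  pass/fail-only mode keeps qualifying reads whole.
* **Threads.** The `aln --threads` flag is accepted for interface
  compatibility but the engine is serial: the contract is that output is
  byte-identical at any thread count, and at desk scale process-level
  parallelism in R would cost more in marshalling than it saves. The
  invariance tests exercise chunking, batching, and the flag.

## What the synthetic generator emulates — and what it does not

`generate_db()` draws i.i.d. residues from the BLOSUM62 background
frequencies; `generate_reads()` excises random fragments, substitutes
residues according to the BLOSUM62 conditional model
(`P(b|a) ∝ p_b·e^{λ_u·s(a,b)}`, ungapped λ_u = 0.3176) down to a target
identity drawn uniformly from 60–90%, applies 1-residue indels at rate
0.005 per residue, reverse-translates with uniformly random synonymous
codons, trims to a uniform 60–75 bp read length, flips a fair coin for
strand, and emits Phred qualities ≈ N(35, 3) truncated to [2, 40]. Each
read's source, interval, frame, and realized identity are recorded in a
truth table.

This emulates the statistics that stress the seed stage — composition,
fragment divergence of moderately diverged homologues, strand symmetry,
partial trailing codons — but not real protein structure: no domain
repeats, low-complexity regions, paralogous families, length-dependent
composition bias, or sequencing-error models. A green sensitivity test
therefore establishes that the candidate search loses few genuinely
alignable reads under BLOSUM62-like divergence; it does not establish
performance on repeat-rich or low-complexity databases, which is exactly
what the exhaustive oracle is shipped to measure case by case.

Fixture defaults (sizes, identity range, indel rate, quality model) were
fixed when the generator was written and are not tuned against test
outcomes.

## Validation design

Every optimized path has an independent oracle in the test suite: the
Rcpp Smith–Waterman kernels are checked cell-for-cell against a naive
full-matrix R implementation; the inverted index against brute-force
substring enumeration; candidate bucketing against hand-traced examples;
and the full pipeline against the exhaustive search. The acceptance
surface measures (1) the analytic chunk count for a 2.0×10⁹-residue
database under a 128×10⁶ limit, (2) recall of ≥ 50-bit oracle best hits
at the reference parameters on the synthetic fixture (expected ≥ 90%),
(3) soundness of the window restriction (restricted score ≤ full score,
equal when the optimum fits the window), (4) completeness of candidate
search at `t = 1, s = 1`, (5) bin-wise monotonicity of sensitivity in
`K`, `s`, `t`, and (6) byte-identical output across chunkings, batch
sizes, and thread counts.

## Known limitations

* Frameshift-tolerant alignment is out of scope: a read with a true
  frameshift aligns as two frames at best.
* Bit scores use fixed gapped constants rather than matrix-derived
  statistics, so absolute parity with other tools' bit scores is not
  guaranteed; comparisons in the package always bin by its own scores.
* The candidate stage counts each (query offset, database position) pair
  once; highly repetitive subjects can still emit several candidates per
  frame, which the per-(read, frame, subject) dedup resolves at
  alignment time.
* `K` is limited to 1–6 by the integer key encoding; the defaults use 4.
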