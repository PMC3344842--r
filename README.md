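# ghostseek

Seed-and-extend translated homology search for short DNA reads against a
protein database, in R.

## The problem

Metagenomic surveys produce millions of short reads (~60–75 bp) from
organisms without close reference genomes. Assigning them to protein
families requires a translated (BLASTX-style) search: each read is
translated in all six reading frames and locally aligned against a
protein database, because homology that is invisible at the nucleotide
level is often plain at the protein level. Exhaustive Smith–Waterman
over every frame × subject pair is the sensitivity gold standard but is
orders of magnitude too slow for survey-scale data.

ghostseek is for people who want a fast, fully inspectable seeded
approximation of that search *together with* the machinery to measure
exactly what the approximation costs: an exhaustive Smith–Waterman
oracle, a synthetic read/database simulator with a truth table, and a
sensitivity harness.

## The algorithm

1. **Index** (`build_chunks`): database sequences are concatenated with
   delimiter sentinels and every K-mer (default K = 4) lying inside a
   single sequence is stored in an inverted index, positions in order of
   appearance. Large databases split greedily into chunks of at most
   `chunk_limit` (default 128×10⁶) residues; chunks are searched
   independently and merged, with byte-identical results for any
   chunking.
2. **Candidate search** (`query_keys`, `find_candidates`): each frame
   contributes keys at every s-th offset (default s = 2). A key match at
   database position p with query offset q predicts an alignment start
   d = p − q. Predicted starts are bucketed into regions of width r
   (default 4); a region plus its right neighbour holding ≥ t matches
   (default 2) emits a candidate anchored at the smallest contributing d.
3. **Restricted alignment** (`align_candidates`): affine-gap
   Smith–Waterman (BLOSUM62, gap open 11 / extend 1) of the frame
   against a window of size m + 2r + 2e around the candidate
   (m = frame length, e = 2), so alignment cost is independent of
   subject length. Raw scores S become bit scores
   (λS − ln k)/ln 2 with the gapped BLOSUM62 constants λ = 0.267,
   k = 0.041. Best hit per (read, frame, subject) is kept; output is the
   12-column BLAST tabular format.

## Worked example

```r
library(ghostseek)

spec <- synthetic_spec(n_db_seqs = 50, db_len_range = c(100, 200),
                       n_reads = 20, target_identity = 1.0,
                       indel_rate = 0, seed = 7)
db  <- generate_db(spec)          # 50 random proteins
gr  <- generate_reads(db, spec)   # 20 reads + truth table

chunks <- build_chunks(db, search_params())
hits   <- search_reads(gr$reads, chunks)
head(hits[, c("read_id", "frame", "subject_id", "raw_score",
              "bit_score", "identity_pct")], 3)
#>     read_id frame subject_id raw_score bit_score identity_pct
#> 1 read00001    -1 dbseq00034       127  53.52858          100
#> 2 read00002     1 dbseq00050       108  46.20979          100
#> 3 read00003     1 dbseq00034       123  51.98778          100

oracle <- full_sw_search(gr$reads, db)   # exhaustive Smith-Waterman
recall_vs_oracle(hits, oracle, min_bits = 50)
#> $recall_pct
#> [1] 100
#> $n_eligible
#> [1] 10
#> $n_recovered
#> [1] 10
```

Each hit row is one local alignment: `raw_score` is the Smith–Waterman
score of the windowed alignment, `bit_score` its Karlin–Altschul
rescaling, and at identity 1.0 every read's best hit is its true source
sequence — which `recall_vs_oracle` confirms against the exhaustive
search (here, all 10 reads whose oracle best hit reaches 50 bits are
recovered).

File-based equivalents, mirroring the reference command lines:

```r
cli(c("db", "-k", "4", "-l", "128", "-i", "proteins.fasta", "-o", "db.gsk"))
cli(c("aln", "-s", "2", "-r", "4", "-e", "2", "-t", "2",
      "-i", "db.gsk", "-q", "reads.fastq", "-o", "hits.tsv"))
```

## Package tour

| file | contents |
|---|---|
| `R/seq_io.R` | FASTA/FASTQ parsing, Q15/60 bp quality filter, blast8 tabular I/O |
| `R/translate.R` | six-frame translation (N→X rule), DNA coordinate back-mapping |
| `R/db_index.R` | chunked k-mer inverted index, save/load |
| `R/seed_search.R` | skip-sampled query keys, region-bucketed candidates |
| `R/local_align.R` | windowed Smith–Waterman, bit scores |
| `R/pipeline.R`, `R/cli.R` | orchestration, `db`/`aln`/`sweep` subcommands |
| `R/synthetic.R`, `R/oracle.R` | simulator, exhaustive oracle, sensitivity curves |
| `src/kernels.cpp` | Rcpp alignment kernels (windowed + score-only scan) |

See `vignettes/ghostseek-methods.Rmd` for the model, parameter meanings,
numerical choices, and what the synthetic benchmark does and does not
establish.
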