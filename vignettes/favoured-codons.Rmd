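---
title: "Detecting favoured codons from raw RNA-seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting favoured codons from raw RNA-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corseqr)
```

## The problem

Synonymous codons are not used uniformly. In many organisms, genes that are
highly expressed are enriched for a subset of *favoured* (optimal) codons —
those matching the most abundant tRNAs — because selection on translational
speed and accuracy acts most strongly where ribosome throughput matters.
The classical way to identify an organism's favoured codons contrasts the
codon usage of its most- and least-expressed genes, which requires a
genome or transcriptome assembly, annotation, read alignment and
expression quantification.

`corseqr` identifies favoured codons from a raw RNA-seq FASTQ file and a
protein training set alone. The idea is that a read's coding frame and
orientation can be inferred by translating it in all six frames and
looking for an exact peptide match against a k-mer index of known
proteins, and that the *frequency* of frame-aligned nucleotide k-mers
across such framed reads is a usable proxy for expression — no
quantification step needed.

## The method

1. **Peptide set** (`build_peptide_set`). Every protein in the training
   set is scanned with a sliding window of `kp` residues (step 1, default
   `kp = 11`); the distinct k-mers form a membership index. Windows
   containing a nonstandard residue (X, B, Z, U, `*`) are dropped
   individually, so a partially ambiguous protein still contributes its
   clean windows.

2. **Pseudo-ORFs** (`sample_reads`, `find_frames`,
   `extract_pseudo_orfs`). Reads are drawn uniformly *with replacement*
   from the FASTQ until `nob` bases (default 20 Mb) accumulate; because
   sampling is proportional to nothing but read multiplicity, abundant
   transcripts dominate the sample just as they dominate the library.
   Each read is scanned at every offset on the forward strand and then on
   the reverse complement for a `3 * kp` = 33-nt window that is pure
   ACGT, translates without a stop under the standard genetic code, and
   whose peptide is in the index. The first qualifying window fixes the
   read's frame and orientation; the read is reverse-complemented if
   needed and trimmed so that position 0 is a codon boundary and the
   length is a multiple of 3. The whole trimmed read — not only the
   matched window — is kept as a *pseudo-ORF*, since the downstream
   k-mer walk assumes a frame-consistent segment.

3. **K-mer quantification** (`count_kmers`, `select_extremes`).
   Frame-aligned nucleotide k-mers (length `k = 39` by default, window
   step fixed at 3 so every k-mer is an in-frame codon string) are
   counted across all pseudo-ORFs. After sorting by count, the top and
   bottom `pct` percent (default 2) of *distinct* k-mers are taken as
   proxies for highly and lowly expressed sequence.

4. **Favoured-codon calls** (`count_codons`, `codon_test`,
   `call_favoured`). Codons are counted in frame 0 over each tail, and
   for every codon of every multi-codon amino-acid family a 2x2
   contingency table is built: codon count versus synonymous-peer count,
   high tail versus low tail. The statistic is the uncorrected Pearson
   chi-square

   $$\chi^2 = \frac{N\,(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

   and the association measure is the odds ratio $ad/bc$. A codon is
   called favoured when the odds ratio exceeds 1 and $\chi^2 > 3.84$,
   the 1-df critical value at $p = 0.05$.

The conventional expression method (`cem_favoured`) applies the same
contingency machinery to the codon usage of the 5% most- versus
least-expressed coding sequences given an expression table, and
`compare_methods` / `replicate_concordance` quantify agreement between
runs and methods (shared calls, odds-ratio direction agreement, Pearson
correlation of odds ratios, amino-acid consensus).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `kp` | 11 residues | peptide k-mer length; the frame-search window is `3*kp` = 33 nt |
| `k` | 39 nt | nucleotide k-mer length; must be a multiple of 3 to stay frame-aligned |
| `nob` | 2e7 bases | read volume sampled (with replacement) from the FASTQ |
| `pct` | 2 % | tail percentage of distinct k-mers used as expression proxies |
| `cem_pct` | 5 % | expression tail for the conventional method |
| chi-square cutoff | 3.84 | 1-df critical value at p = 0.05; no multiple-testing correction |

`kp = 11` makes chance peptide matches vanishingly rare (a random 11-mer
hits a given index entry with probability $20^{-11}$ per window) while
keeping the 33-nt window short enough to fit several times into a
100–150-nt read. `k = 39` is long enough that a k-mer is effectively
transcript-specific, and short enough to recur across overlapping reads
of the same transcript.

## Numerical and design choices

* **First match wins.** When a read qualifies at several offsets, the
  forward strand is scanned before the reverse complement and lower
  offsets win. All same-strand matches of a genuine coding read imply
  the same frame, so the rule only matters for pathological reads; it
  makes the pipeline deterministic and cheap.
* **Tie-breaking in the tails.** At realistic depths the low tail
  consists almost entirely of count-1 k-mers, so *which* singletons
  enter the tail is decided by the tie rule. An alphabetical tie order
  packs the low tail with A-leading k-mers and visibly distorts its
  codon composition; `corseqr` instead orders ties by a fixed FNV-1a
  hash of the k-mer string. The selection stays bit-reproducible across
  runs and platforms but is compositionally neutral, like a random
  subsample with a frozen seed.
* **Occurrence weighting (default on).** Codon counts over a tail can
  weight each distinct k-mer by its occurrence count or count it once.
  Weighting is the default: it keeps the high tail dominated by truly
  abundant sequence however wide the tail is, and in validation it is
  what makes the favoured set stable across the whole supported
  `pct` range (1–15%). Unweighted counting is available via
  `weight_by_count = FALSE`; in our experiments it inverts the calls at
  `pct >= 5` because the widening high tail dilutes into
  moderately expressed genes while the singleton low tail keeps tracking
  abundant (error-bearing) sequence.
* **Odds ratios at zero cells.** The Haldane–Anscombe correction (+0.5
  on every cell) is applied to the odds ratio only when some cell is
  zero, keeping it finite; the chi-square statistic is never corrected,
  and is defined as 0 when a codon margin is empty.
* **No continuity or multiplicity correction.** The 3.84 cutoff is the
  uncorrected chi-square critical value and is applied per codon; counts
  are large, and a fixed threshold mirrors standard practice for this
  statistic.
* **Stops and single-codon families.** Stop triplets are tallied but
  excluded from family totals; ATG (Met) and TGG (Trp) have no
  synonymous peers and are never testable.
* **Genetic code.** The standard code (translation table 1) is used for
  all inputs.
* **Coordinates.** All offsets are 0-based and half-open internally.

## The synthetic validation data

`synthetic_truth` / `generate_transcriptome` / `simulate_reads` build a
ground-truthed study: one planted favoured codon per multi-codon family;
random proteins back-translated codon by codon, with genes in the top
expression decile drawing each family's codon with planted mass
`bias_high = 0.7` (the rest uniform); log-normal expression with
`sdlog = 1.8`, giving roughly a 100-fold interdecile range as in real
RNA-seq libraries; and fixed-length reads drawn proportionally to
abundance times length, on a uniform strand, with 0.5% substitution
errors. The standard validation conditions are 500 genes of 80–400
residues and 200,000 reads of 100 nt (20 Mb, the pipeline's default
`nob`); the unit-test fixtures use a miniature 80-gene / 2-Mb version so
the suite stays fast.

What the generator does *not* emulate: indels (which would break frame
inference), quality-correlated or positionally biased errors, coverage
bias, paired-end structure, alternative genetic codes, and a continuous
expression–bias relationship (the planted bias is a sharp top-decile
contrast). Passing tests therefore demonstrate correct mechanics and
recoverability under idealized read structure, not performance on any
particular real library.

## Null behaviour and known limitations

On null data (no codon/expression association) the pipeline calls more
codons "favoured" than the nominal 5% level suggests — about a third of
testable codons under the default weighted counting on the standard null
fixture, and roughly 10–20% unweighted. This is intrinsic to the test's
assumptions, not a defect of the arithmetic: overlapping step-3 k-mers
count the same transcript codon position up to `k/3` = 13 times, and
each tail clusters on a modest number of genes whose finite-length
realized codon usage deviates from the population distribution. Both
effects make the effective sample size far smaller than the nominal
counts (1e5–1e6 codons per tail), so the chi-square is anticonservative
under the null. In practice the method is used where a strong biological
signal exists, and the planted-signal validation shows calls then
concentrate on the true favoured set; but isolated calls on weak-signal
data should not be over-interpreted, and the per-codon `p_value` column
must not be read as a calibrated error rate.

Other limitations: single-end reads only; no quality filtering or
trimming (by design — the frame search itself discards windows that do
not translate cleanly); training proteins must be close enough to the
organism that exact 11-mer peptide matches occur; and transcripts
shorter than the 33-nt search window can never be framed.

## Reproducibility

Every stochastic step (read sampling, dataset generation, read
simulation) takes an explicit integer seed and restores the caller's RNG
state. A pipeline run records its full configuration, seed and stage
counts in the report header, so any report can be regenerated exactly.
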