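#' Run the full favoured-codon pipeline on a FASTQ file
#'
#' Composes the whole method: build (or load) the amino-acid kmer index
#' from the protein training set, sample `nob` bases of reads with
#' replacement, infer each read's coding frame and orientation against the
#' index, cut the matched reads into pseudo-ORFs, count frame-aligned
#' nucleotide `k`-mers (step 3), select the top and bottom `pct` percent of
#' distinct kmers as high/low expression proxies, count codons in each
#' tail, and call favoured codons with the per-codon 2x2 chi-square / odds
#' ratio rule. Stage counts (reads sampled, reads matched, distinct kmers,
#' tail sizes) are logged to stderr and stored in the report metadata.
#'
#' @param fastq FASTQ path (plain or gzipped).
#' @param proteins Protein training set: FASTA path, sequences, or a
#'   prebuilt `peptide_set` (then `kp` is taken from it).
#' @param kp Amino-acid kmer length (default 11).
#' @param k Nucleotide kmer length, multiple of 3 (default 39).
#' @param nob Number of bases to sample (default 2e7).
#' @param pct Kmer-tail percentage (default 2).
#' @param seed Integer seed for read sampling.
#' @param weight_by_count Weight tail codon counts by each kmer's
#'   occurrence count (default on). Occurrence weighting keeps the high
#'   tail anchored to the truly abundant kmers, which is what makes the
#'   favoured set stable across the whole supported `pct` range; set to
#'   `FALSE` to count each distinct tail kmer once.
#' @param quiet Suppress stage messages.
#' @return A `favoured_codon_report` (see [call_favoured()]) whose metadata
#'   records the full configuration, seed and stage counts.
#' @export
run_pipeline <- function(fastq, proteins,
                         kp = corseq_defaults()$kp,
                         k = corseq_defaults()$k,
                         nob = corseq_defaults()$nob,
                         pct = corseq_defaults()$pct,
                         seed = 1L, weight_by_count = TRUE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[corseqr] ", sprintf(...))

  index <- if (inherits(proteins, "peptide_set")) proteins
           else build_peptide_set(proteins, kp)
  kp <- index$kp
  say("peptide index: %d distinct %d-mers from %d proteins",
      length(index$kmers), kp, index$n_source_proteins)

  smp <- sample_reads(fastq, nob = nob, seed = seed)
  say("sampled %d reads (%d bases, target %g)",
      length(smp$sequence), smp$total_bases, smp$nob_target)

  frames <- find_frames(smp$sequence, index)
  n_matched <- sum(!is.na(frames$orientation))
  say("frame found for %d / %d reads (%.1f%%)", n_matched,
      length(smp$sequence), 100 * n_matched / length(smp$sequence))
  if (n_matched == 0L)
    stop("frame search: no read matched the peptide index", call. = FALSE)
  orfs <- extract_pseudo_orfs(smp$sequence, frames)

  tab <- count_kmers(orfs, k)
  say("%d distinct %d-mers counted across %d pseudo-ORFs",
      length(tab$counts), k, length(orfs))
  ext <- select_extremes(tab, pct)
  say("tails: %d high / %d low distinct kmers (pct = %g)",
      length(ext$high), length(ext$low), pct)

  high_counts <- count_codons(ext$high,
                              if (weight_by_count) ext$high_counts)
  low_counts <- count_codons(ext$low,
                             if (weight_by_count) ext$low_counts)
  report <- call_favoured(high_counts, low_counts, meta = list(
    method = "corseq", fastq = fastq, kp = kp, k = k, nob = nob,
    pct = pct, seed = seed, weight_by_count = weight_by_count,
    n_reads_sampled = length(smp$sequence), n_reads_matched = n_matched,
    n_distinct_kmers = length(tab$counts),
    tail_size = length(ext$high)))
  say("%d favoured codons called", length(favoured_codons(report)))
  report
}
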