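#' Count frame-aligned nucleotide kmers across pseudo-ORFs
#'
#' Slides a window of `k` bases with step 3 (codon boundaries) over every
#' pseudo-ORF and aggregates occurrence counts. Because pseudo-ORFs are
#' frame-consistent and the step is 3, every kmer is an in-frame codon
#' sequence. Windows containing non-ACGT characters are skipped.
#'
#' @param pseudo_orfs Character vector of pseudo-ORF sequences (from
#'   [extract_pseudo_orfs()]).
#' @param k Kmer length in bases; must be a positive multiple of 3
#'   (default 39).
#' @return A `kmer_count_table`: list with `k` and `counts`, a named integer
#'   vector (kmer -> occurrence count).
#' @export
count_kmers <- function(pseudo_orfs, k = corseq_defaults()$k) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 3L != 0L)
    stop("`k` must be a positive multiple of 3 (frame alignment)",
         call. = FALSE)
  res <- cpp_count_kmers(as.character(pseudo_orfs), k)
  counts <- res$count
  names(counts) <- res$kmer
  structure(list(k = k, counts = counts), class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table: %d distinct %d-mers, %.0f occurrences\n",
              length(x$counts), x$k, sum(as.numeric(x$counts))))
  invisible(x)
}

#' Select the extreme-frequency kmer tails
#'
#' Sorts the distinct kmers by occurrence count (ascending) and takes the
#' bottom and top `pct` percent as proxies for lowly and highly expressed
#' genes. Tail size is `ceiling(pct/100 * n_distinct)`, minimum 1. Ties —
#' ubiquitous among count-1 kmers — are broken by a fixed FNV-1a hash of
#' the kmer string (with C-locale string order as final fallback): the
#' selection is fully deterministic across runs yet compositionally
#' neutral, whereas an alphabetical tie order would pack the low tail with
#' A-leading kmers and bias the downstream codon counts.
#'
#' @param table A `kmer_count_table` from [count_kmers()].
#' @param pct Tail percentage, in (0, 50) (default 2).
#' @return An `extreme_kmer_sets`: list with `high` and `low` (character
#'   vectors of distinct kmers), `high_counts` / `low_counts` (their
#'   occurrence counts), and `pct`.
#' @export
select_extremes <- function(table, pct = corseq_defaults()$pct) {
  stopifnot(inherits(table, "kmer_count_table"))
  if (!is.numeric(pct) || pct <= 0 || pct >= 50)
    stop("`pct` must be in (0, 50)", call. = FALSE)
  n <- length(table$counts)
  if (n == 0L) stop("kmer table is empty", call. = FALSE)
  size <- max(1L, as.integer(ceiling(pct / 100 * n)))
  if (n <= 2L * size)
    stop("only ", n, " distinct kmers: tails of size ", size,
         " would overlap; increase NOB or decrease pct", call. = FALSE)
  kmers <- names(table$counts)
  ord <- order(table$counts, cpp_fnv1a(kmers), kmers, method = "radix")
  low_i <- ord[seq_len(size)]
  high_i <- ord[seq.int(n - size + 1L, n)]
  structure(list(high = kmers[high_i], low = kmers[low_i],
                 high_counts = unname(table$counts[high_i]),
                 low_counts = unname(table$counts[low_i]),
                 pct = pct),
            class = "extreme_kmer_sets")
}

#' @export
print.extreme_kmer_sets <- function(x, ...) {
  cat(sprintf(
    "extreme_kmer_sets: %d high / %d low distinct kmers (pct = %g)\n",
    length(x$high), length(x$low), x$pct))
  invisible(x)
}
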