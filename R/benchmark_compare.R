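#' Compare two favoured-codon reports
#'
#' Computes the standard benchmark metrics between two method runs:
#' the number of favoured codons called by both and by each method only;
#' the fraction of mutually testable codons whose odds ratios fall on the
#' same side of 1 (> 1 in both or < 1 in both); the Pearson correlation of
#' the raw odds-ratio vectors over mutually testable codons; and the
#' amino-acid consensus (AAC) — among amino acids for which both methods
#' favoured at least one codon, the fraction sharing at least one favoured
#' codon.
#'
#' @param a,b `favoured_codon_report` objects built under the same genetic
#'   code.
#' @return A `comparison_metrics` list: `n_common`, `n_only_a`, `n_only_b`,
#'   `same_direction_fraction`, `pearson_r`, `aac`, `n_mutually_testable`.
#' @export
compare_methods <- function(a, b) {
  stopifnot(inherits(a, "favoured_codon_report"),
            inherits(b, "favoured_codon_report"))
  fa <- favoured_codons(a)
  fb <- favoured_codons(b)
  common <- intersect(fa, fb)

  shared <- merge(
    a[a$testable, c("codon", "amino_acid", "odds_ratio")],
    b[b$testable, c("codon", "odds_ratio")],
    by = "codon", suffixes = c("_a", "_b"))
  if (nrow(shared) == 0L)
    stop("no mutually testable codons", call. = FALSE)
  same_dir <- mean((shared$odds_ratio_a > 1 & shared$odds_ratio_b > 1) |
                   (shared$odds_ratio_a < 1 & shared$odds_ratio_b < 1))
  r <- if (nrow(shared) >= 3L)
    stats::cor(shared$odds_ratio_a, shared$odds_ratio_b) else NA_real_

  aa_of <- function(rep, codons) unique(rep$amino_acid[rep$codon %in% codons])
  aa_a <- aa_of(a, fa)
  aa_b <- aa_of(b, fb)
  aa_both <- intersect(aa_a, aa_b)
  aa_shared <- aa_of(a, common)
  aac <- if (length(aa_both)) mean(aa_both %in% aa_shared) else NA_real_

  structure(list(n_common = length(common),
                 n_only_a = length(setdiff(fa, fb)),
                 n_only_b = length(setdiff(fb, fa)),
                 same_direction_fraction = same_dir,
                 pearson_r = r,
                 aac = aac,
                 n_mutually_testable = nrow(shared)),
            class = "comparison_metrics")
}

#' @export
print.comparison_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("comparison_metrics: common %d | only A %d | only B %d | ",
           "same OR direction %.3f | Pearson r %.3f | AAC %.3f\n"),
    x$n_common, x$n_only_a, x$n_only_b, x$same_direction_fraction,
    x$pearson_r, x$aac))
  invisible(x)
}

#' Replicate concordance of favoured-codon calls
#'
#' Given reports from runs differing only in the sampling seed, returns how
#' many replicates called each codon favoured and the fully concordant core
#' set (codons favoured in every replicate).
#'
#' @param reports List of at least two `favoured_codon_report` objects.
#' @return List with `counts` (named integer vector over codons favoured in
#'   at least one replicate), `core` (character vector) and `n_replicates`.
#' @export
replicate_concordance <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2L,
            all(vapply(reports, inherits, NA, "favoured_codon_report")))
  sets <- lapply(reports, favoured_codons)
  all_calls <- sort(unique(unlist(sets)))
  counts <- vapply(all_calls, function(cd)
    sum(vapply(sets, function(s) cd %in% s, NA)), 1L)
  list(counts = counts,
       core = all_calls[counts == length(reports)],
       n_replicates = length(reports))
}
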