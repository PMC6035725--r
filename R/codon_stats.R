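#' Count in-frame codons over a set of kmers or coding sequences
#'
#' Each sequence is read in frame 0 as consecutive triplets. Counts
#' accumulate across sequences, optionally weighted. Sequences containing
#' non-ACGT characters (or whose length is not a multiple of 3) are skipped
#' with a warning. Stop-codon triplets are tallied but reported separately:
#' they never enter an amino-acid family.
#'
#' @param kmers Character vector of nucleotide sequences, each a multiple of
#'   3 long.
#' @param weights Optional positive integer weights, one per sequence
#'   (occurrence counts when weighting kmer tails by frequency).
#' @return Named numeric vector of counts over the 61 coding codons, with
#'   attributes `stop_counts` (counts of TAA/TAG/TGA) and `skipped` (number
#'   of skipped sequences).
#' @export
#' @examples
#' count_codons(c("GCTGCAGCT"))
count_codons <- function(kmers, weights = NULL) {
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(kmers), all(weights >= 1))
    weights <- as.integer(weights)
  } else weights <- integer(0)
  res <- cpp_count_codons(as.character(kmers), weights)
  counts <- res$count
  names(counts) <- res$codon
  if (res$skipped > 0L)
    warning(res$skipped,
            " sequence(s) skipped (non-ACGT or length not a multiple of 3)",
            call. = FALSE)
  stops <- c("TAA", "TAG", "TGA")
  structure(counts[setdiff(names(counts), stops)],
            stop_counts = counts[stops], skipped = res$skipped)
}

#' Per-codon 2x2 contingency test between expression proxies
#'
#' The table contrasts a codon against its synonymous peers across the two
#' groups: the first row holds the codon count `a` and the peers count `b`
#' in the high-frequency group, the second row the same counts `c`, `d` in
#' the low-frequency group. The statistic is the uncorrected Pearson
#' chi-square, `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' `N = a+b+c+d` and no continuity correction (the decision cutoff 3.84 is
#' the uncorrected 1-df critical value); it is 0 when a codon margin
#' (`a+c` or `b+d`) is zero. The odds ratio is `ad / bc`, with the
#' Haldane-Anscombe 0.5 added to every cell only when some cell is zero
#' (and only for the odds ratio, never the statistic).
#'
#' All four arguments are recycled, so vectors of tables are tested in one
#' call.
#'
#' @param a,b,c,d Nonnegative counts; `a+b > 0` and `c+d > 0` required.
#' @return Data frame with columns `odds_ratio` and `chi_square`.
#' @export
#' @examples
#' codon_test(90, 10, 50, 50) # odds_ratio 9, chi_square ~38.095
codon_test <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(a < 0 | b < 0 | c < 0 | d < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (any(a + b <= 0 | c + d <= 0))
    stop("each group must contain the amino-acid family (a+b > 0, c+d > 0)",
         call. = FALSE)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi <- ifelse(denom == 0, 0, n * (a * d - b * c)^2 / denom)
  adj <- (a == 0 | b == 0 | c == 0 | d == 0) * 0.5
  or <- ((a + adj) * (d + adj)) / ((b + adj) * (c + adj))
  data.frame(odds_ratio = or, chi_square = chi)
}

#' Call favoured codons from high- and low-group codon counts
#'
#' For every codon of every multi-codon amino-acid family, builds the 2x2
#' table (`a` = codon count in the high group, `b` = family total minus `a`,
#' `c`/`d` likewise in the low group), runs [codon_test()], and flags the
#' codon as favoured when the odds ratio exceeds 1 and the chi-square
#' exceeds 3.84 (p < 0.05 at 1 df). Single-codon families (ATG/Met,
#' TGG/Trp) and stop codons are never testable. Codons whose family is
#' absent from either group are kept in the report with `testable = FALSE`
#' and NA statistics.
#'
#' @param high_counts,low_counts Named codon count vectors from
#'   [count_codons()] on the high and low groups.
#' @param meta Optional named list of run metadata stored in the report
#'   (parameters, seed, input paths).
#' @return A `favoured_codon_report`: data frame with one row per codon of
#'   each multi-codon family, columns `codon`, `amino_acid`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `chi_square`, `p_value`, `favoured`, `testable`,
#'   sorted by amino acid then codon; run metadata in `attr(, "meta")`.
#' @export
call_favoured <- function(high_counts, low_counts, meta = list()) {
  fams <- multi_codon_families()
  gc <- genetic_code_map()
  if (sum(high_counts[names(high_counts) %in% unlist(fams)]) == 0)
    stop("high group contains no usable codons; increase NOB",
         call. = FALSE)
  if (sum(low_counts[names(low_counts) %in% unlist(fams)]) == 0)
    stop("low group contains no usable codons; increase NOB",
         call. = FALSE)
  cnt <- function(x, codon) {
    v <- x[codon]
    ifelse(is.na(v), 0, as.numeric(v))
  }
  rows <- lapply(names(fams), function(aa) {
    codons <- sort(fams[[aa]])
    a <- vapply(codons, function(cd) cnt(high_counts, cd), 1)
    c_ <- vapply(codons, function(cd) cnt(low_counts, cd), 1)
    data.frame(codon = codons, amino_acid = aa,
               a = a, b = sum(a) - a, c = c_, d = sum(c_) - c_,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$amino_acid, rep$codon, method = "radix"), ]
  rownames(rep) <- NULL
  rep$testable <- (rep$a + rep$b) > 0 & (rep$c + rep$d) > 0
  rep$odds_ratio <- rep$chi_square <- rep$p_value <- NA_real_
  rep$favoured <- NA
  if (any(!rep$testable))
    message(sum(!rep$testable),
            " codon(s) untestable: family absent from one of the groups")
  t_ <- rep$testable
  if (any(t_)) {
    res <- codon_test(rep$a[t_], rep$b[t_], rep$c[t_], rep$d[t_])
    rep$odds_ratio[t_] <- res$odds_ratio
    rep$chi_square[t_] <- res$chi_square
    rep$p_value[t_] <- pchisq(res$chi_square, df = 1, lower.tail = FALSE)
    rep$favoured[t_] <- res$odds_ratio > 1 &
      res$chi_square > corseq_defaults()$chi_cutoff
  }
  rep <- rep[, c("codon", "amino_acid", "a", "b", "c", "d", "odds_ratio",
                 "chi_square", "p_value", "favoured", "testable")]
  structure(rep, meta = meta,
            class = c("favoured_codon_report", "data.frame"))
}

#' Extract the favoured codon set from a report
#'
#' @param report A `favoured_codon_report`.
#' @return Character vector of favoured codons.
#' @export
favoured_codons <- function(report) {
  report$codon[!is.na(report$favoured) & report$favoured]
}

#' @export
print.favoured_codon_report <- function(x, ...) {
  fav <- favoured_codons(x)
  cat(sprintf(
    "favoured_codon_report: %d codons tested, %d favoured\n",
    sum(x$testable), length(fav)))
  if (length(fav)) {
    by_aa <- split(fav, x$amino_acid[match(fav, x$codon)])
    cat("favoured:",
        paste(sprintf("%s:%s", names(by_aa),
                      vapply(by_aa, paste, "", collapse = ",")),
              collapse = " "), "\n")
  }
  NextMethod()
}

#' Write / read a favoured-codon report as TSV
#'
#' The report is self-describing: run metadata (parameters, seed, inputs)
#' is carried as `# key=value` comment lines above the header.
#'
#' @param report A `favoured_codon_report`.
#' @param path TSV file path.
#' @return `write_codon_report()`: `path`, invisibly;
#'   `read_codon_report()`: the report.
#' @export
write_codon_report <- function(report, path) {
  stopifnot(inherits(report, "favoured_codon_report"))
  meta <- attr(report, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s=%s", key,
                       paste(format(meta[[key]], scientific = FALSE),
                             collapse = ",")), con)
  write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_codon_report
#' @export
read_codon_report <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  rep <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  structure(rep, meta = meta,
            class = c("favoured_codon_report", "data.frame"))
}
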