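#' Read a transcript expression table (TSV)
#'
#' Two columns, `transcript_id <tab> abundance`; a header line is accepted
#' and detected by a non-numeric second field.
#'
#' @param path TSV path.
#' @return Named numeric vector of abundances.
#' @export
read_expression_table <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L])))
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE,
                    col.names = c("transcript_id", "abundance"))
  expr <- tab$abundance
  names(expr) <- tab$transcript_id
  if (any(is.na(expr)) || any(expr < 0))
    stop("abundances must be nonnegative numbers", call. = FALSE)
  expr
}

#' Favoured codons by the conventional expression method (CEM)
#'
#' Contrasts the codon usage of the most- versus least-expressed coding
#' sequences: transcripts are sorted by abundance (descending, id as
#' tiebreak), the top and bottom `pct` percent form the high and low sets,
#' codons are counted over the full CDSs of each set, and the same per-codon
#' 2x2 contingency machinery and odds ratio > 1 / chi-square > 3.84 rule as
#' the kmer pipeline calls the favoured codons. Alignment and abundance
#' estimation are not performed here; abundances are an input.
#'
#' CDSs whose length is not a multiple of 3 or that contain an internal
#' stop codon are dropped with a logged count.
#'
#' @param cds CDS multi-FASTA path, `DNAStringSet`, or named character
#'   vector of coding sequences.
#' @param expr Named numeric abundances (or a TSV path for
#'   [read_expression_table()]); ids must cover the CDS ids.
#' @param pct Expression-tail percentage (default 5).
#' @return A `favoured_codon_report` (see [call_favoured()]).
#' @export
cem_favoured <- function(cds, expr, pct = corseq_defaults()$cem_pct) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- Biostrings::readDNAStringSet(cds)
  nm <- names(cds)
  if (is.null(nm)) stop("CDS sequences must carry unique ids", call. = FALSE)
  seqs <- structure(toupper(as.character(cds)),
                    names = sub("\\s.*$", "", nm))
  if (anyDuplicated(names(seqs)))
    stop("CDS sequences must carry unique ids", call. = FALSE)
  if (is.character(expr) && length(expr) == 1L && file.exists(expr))
    expr <- read_expression_table(expr)

  ok_len <- nchar(seqs) %% 3L == 0L
  internal_stop <- vapply(seqs[ok_len], function(s) {
    n <- nchar(s)
    if (n < 6L) return(FALSE)
    cods <- substring(s, seq(1L, n - 3L, 3L), seq(3L, n - 3L + 2L, 3L))
    any(cods %in% c("TAA", "TAG", "TGA"))
  }, NA)
  drop <- sum(!ok_len) + sum(internal_stop)
  if (drop > 0L)
    message(drop, " CDS(s) dropped (length not a multiple of 3 or ",
            "internal stop)")
  seqs <- seqs[ok_len][!internal_stop]
  if (length(seqs) == 0L) stop("no usable CDSs", call. = FALSE)

  missing <- setdiff(names(seqs), names(expr))
  if (length(missing))
    stop("transcripts missing from the expression table: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ...", call. = FALSE)
  expr <- expr[names(seqs)]

  n <- length(seqs)
  size <- max(1L, as.integer(ceiling(pct / 100 * n)))
  if (n <= 2L * size)
    stop("only ", n, " transcripts: ", pct, "% tails would overlap",
         call. = FALSE)
  ord <- order(-expr, names(seqs), method = "radix")
  high_ids <- names(seqs)[ord[seq_len(size)]]
  low_ids <- names(seqs)[ord[seq.int(n - size + 1L, n)]]

  high_counts <- count_codons(unname(seqs[high_ids]))
  low_counts <- count_codons(unname(seqs[low_ids]))
  call_favoured(high_counts, low_counts,
                meta = list(method = "cem", cem_pct = pct,
                            n_transcripts = n, n_high = size, n_low = size))
}
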