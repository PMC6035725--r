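#' Parameters for a ground-truthed synthetic transcriptome
#'
#' Defines the conditions for a simulated favoured-codon study: one planted
#' favoured codon per multi-codon amino-acid family (chosen under `seed`),
#' a heavy-tailed log-normal expression law, and biased codon usage in the
#' highly expressed genes. Genes in the top expression decile draw each
#' family's codon with the planted codon carrying probability `bias_high`
#' (remaining mass uniform over the peers); all other genes use `bias_low`
#' (default: uniform within the family, i.e. no preference).
#'
#' The default log-normal `sdlog = 1.8` gives roughly a 100-fold ratio
#' between the 90th and 10th expression percentiles, echoing the skew of
#' real RNA-seq libraries.
#'
#' @param n_genes Number of genes (default 500).
#' @param bias_high Planted-codon probability mass within its family in
#'   highly expressed genes (default 0.7); `NULL` means uniform, giving a
#'   null dataset with no codon/expression association.
#' @param bias_low Planted-codon mass in the remaining genes; `NULL` means
#'   uniform within the family.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param protein_length_range Min/max protein length in residues.
#' @param read_length,n_reads,error_rate Read simulation defaults used by
#'   [write_synthetic_dataset()].
#' @param seed Integer seed; the whole dataset regenerates bit-identically
#'   from `(parameters, seed)`.
#' @return A `synthetic_truth` list, including `planted_favoured` (named by
#'   amino acid).
#' @export
synthetic_truth <- function(n_genes = 500L, bias_high = 0.7,
                            bias_low = NULL, expr_meanlog = 1,
                            expr_sdlog = 1.8,
                            protein_length_range = c(80L, 400L),
                            read_length = 100L, n_reads = 200000L,
                            error_rate = 0.005, seed = 1L) {
  stopifnot(n_genes >= 40L,
            is.null(bias_high) || (bias_high > 0 && bias_high <= 1),
            is.null(bias_low) || (bias_low > 0 && bias_low <= 1),
            expr_sdlog > 0, error_rate >= 0, error_rate < 1,
            read_length >= 3L, n_reads >= 1L,
            length(protein_length_range) == 2L,
            protein_length_range[1L] >= ceiling(read_length / 3))
  fams <- multi_codon_families()
  planted <- with_seed(seed, vapply(fams, function(cs) sample(cs, 1L), ""))
  structure(list(planted_favoured = planted,
                 bias_high = bias_high, bias_low = bias_low,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 n_genes = as.integer(n_genes),
                 protein_length_range = as.integer(protein_length_range),
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Family codon-sampling probabilities with the planted codon carrying mass
# `bias` (NULL = uniform).
family_probs <- function(codons, planted, bias) {
  f <- length(codons)
  if (is.null(bias)) return(rep(1 / f, f))
  p <- rep((1 - bias) / (f - 1), f)
  p[codons == planted] <- bias
  p
}

#' Generate a ground-truthed transcriptome
#'
#' Genes are random amino-acid sequences back-translated codon by codon:
#' genes in the top expression decile draw each family's codon from the
#' biased distribution (planted codon mass = `bias_high`), the rest from
#' `bias_low`. Every CDS starts with ATG, ends with a stop codon, and
#' translates without internal stops. The emitted proteins are the exact
#' translations and serve as the training set for the kmer pipeline;
#' expression values are log-normal abundances usable as CEM truth.
#'
#' @param truth A `synthetic_truth`.
#' @return List with `cds` (named character), `proteins` (named character),
#'   `expression` (named numeric) and `truth`.
#' @export
generate_transcriptome <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  fams <- multi_codon_families()
  single <- list(M = "ATG", W = "TGG")
  with_seed(truth$seed + 1L, {
    n <- truth$n_genes
    ids <- sprintf("g%04d", seq_len(n))
    expr <- rlnorm(n, truth$expr_meanlog, truth$expr_sdlog)
    names(expr) <- ids
    high <- rank(-expr, ties.method = "first") <= ceiling(n / 10)

    len <- sample(seq(truth$protein_length_range[1L],
                      truth$protein_length_range[2L]), n, replace = TRUE)
    aas <- c(names(fams), names(single))
    gene_of <- rep.int(seq_len(n), len)
    aa_seq <- sample(aas, sum(len), replace = TRUE)

    codons <- character(length(aa_seq))
    for (aa in aas) {
      pos <- which(aa_seq == aa)
      if (!length(pos)) next
      if (aa %in% names(single)) {
        codons[pos] <- single[[aa]]
        next
      }
      cs <- fams[[aa]]
      hi <- high[gene_of[pos]]
      p_hi <- family_probs(cs, truth$planted_favoured[[aa]],
                           truth$bias_high)
      p_lo <- family_probs(cs, truth$planted_favoured[[aa]],
                           truth$bias_low)
      if (any(hi))
        codons[pos[hi]] <- sample(cs, sum(hi), replace = TRUE, prob = p_hi)
      if (any(!hi))
        codons[pos[!hi]] <- sample(cs, sum(!hi), replace = TRUE,
                                   prob = p_lo)
    }
    body <- vapply(split(codons, gene_of), paste, "", collapse = "")
    stops <- sample(c("TAA", "TAG", "TGA"), n, replace = TRUE)
    cds <- paste0("ATG", body, stops)
    names(cds) <- ids
    proteins <- paste0("M", vapply(split(aa_seq, gene_of), paste, "",
                                   collapse = ""))
    names(proteins) <- ids
    list(cds = cds, proteins = proteins, expression = expr, truth = truth)
  })
}

#' Simulate error-bearing fixed-length RNA-seq reads
#'
#' Reads are drawn from transcripts with probability proportional to
#' abundance times length, with uniform start positions, a uniformly chosen
#' strand (reverse-complemented for minus), per-base substitution errors at
#' `error_rate` (no indels), and a constant quality string. Output is
#' byte-identical for identical inputs and seed.
#'
#' @param cds Named character vector (or `DNAStringSet`, or FASTA path) of
#'   transcript sequences; every one at least `read_length` long.
#' @param expr Named numeric abundances covering the transcripts.
#' @param read_length Read length in bases.
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param out Optional FASTQ path (gzipped if it ends in `.gz`); when
#'   `NULL` the reads are returned invisibly instead.
#' @return Named character vector of reads (names are read ids), invisibly;
#'   written to `out` when given.
#' @export
simulate_reads <- function(cds, expr, read_length = 100L, n_reads = 200000L,
                           error_rate = 0.005, seed = 1L, out = NULL) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- Biostrings::readDNAStringSet(cds)
  nm <- names(cds)
  seqs <- structure(toupper(as.character(cds)),
                    names = sub("\\s.*$", "", nm))
  len <- nchar(seqs)
  if (read_length > min(len))
    stop("read_length exceeds the shortest transcript", call. = FALSE)
  expr <- expr[names(seqs)]
  if (any(is.na(expr))) stop("abundances missing for some transcripts",
                             call. = FALSE)

  reads <- with_seed(seed, {
    ti <- sample.int(length(seqs), n_reads, replace = TRUE,
                     prob = expr * len)
    start <- floor(runif(n_reads) * (len[ti] - read_length + 1)) + 1L
    r <- substr(seqs[ti], start, start + read_length - 1L)
    minus <- runif(n_reads) < 0.5
    r[minus] <- cpp_revcomp(r[minus])

    n_err <- rbinom(n_reads, read_length, error_rate)
    if (any(n_err > 0)) {
      ri <- rep.int(which(n_err > 0), n_err[n_err > 0])
      pos <- floor(runif(length(ri)) * read_length) + 1L
      dup <- duplicated(cbind(ri, pos))
      ri <- ri[!dup]; pos <- pos[!dup]
      bases <- c("A", "C", "G", "T")
      old <- match(substr(r[ri], pos, pos), bases)
      new <- bases[(old - 1L + sample.int(3L, length(ri),
                                          replace = TRUE)) %% 4L + 1L]
      # multiple errors can hit the same read: apply in rounds so no
      # whole-element assignment overwrites an earlier substitution
      round_of <- stats::ave(ri, ri, FUN = seq_along)
      for (rd in seq_len(max(round_of))) {
        sel <- round_of == rd
        tmp <- r[ri[sel]]
        substr(tmp, pos[sel], pos[sel]) <- new[sel]
        r[ri[sel]] <- tmp
      }
    }
    names(r) <- sprintf("r%07d_%s_%d_%s", seq_len(n_reads), names(seqs)[ti],
                        start, ifelse(minus, "m", "p"))
    r
  })

  if (!is.null(out)) {
    x <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::BStringSet(rep(strrep("I", read_length),
                                    length(reads)))
    Biostrings::writeXStringSet(x, out, format = "fastq", qualities = q,
                                compress = endsWith(out, ".gz"))
  }
  invisible(reads)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `cds.fa`, `proteins.fa`, `abundance.tsv`, `reads.fastq` and
#' `truth.json` (all plain text) generated from the truth parameters.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @return Named list of the file paths, invisibly.
#' @export
write_synthetic_dataset <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- generate_transcriptome(truth)
  paths <- list(cds = file.path(dir, "cds.fa"),
                proteins = file.path(dir, "proteins.fa"),
                abundance = file.path(dir, "abundance.tsv"),
                reads = file.path(dir, "reads.fastq"),
                truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx$cds), paths$cds)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(tx$proteins),
                              paths$proteins)
  write.table(data.frame(transcript_id = names(tx$expression),
                         abundance = tx$expression),
              paths$abundance, sep = "\t", quote = FALSE,
              row.names = FALSE)
  simulate_reads(tx$cds, tx$expression, truth$read_length, truth$n_reads,
                 truth$error_rate, seed = truth$seed + 2L,
                 out = paths$reads)
  jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
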