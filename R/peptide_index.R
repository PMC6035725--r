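#' Build the amino-acid kmer index ("peptide set") from a protein training set
#'
#' Slides a window of `kp` residues (step 1) over every protein in the
#' training set and collects the distinct kmers. Sequences are uppercased
#' first; windows containing any character outside the 20 standard amino-acid
#' letters (X, B, Z, U, `*`, ...) are dropped, the rest of the protein still
#' contributes. Proteins shorter than `kp` contribute nothing.
#'
#' @param proteins Path to a protein multi-FASTA file (plain or gzipped), an
#'   `AAStringSet`, or a character vector of amino-acid sequences.
#' @param kp Amino-acid kmer length (default 11).
#' @return A `peptide_set` object: list with `kp`, `kmers` (character vector
#'   of distinct kmers) and `n_source_proteins`.
#' @export
#' @examples
#' build_peptide_set(c("MKVLA", "AKVLM"), kp = 3)
build_peptide_set <- function(proteins, kp = corseq_defaults()$kp) {
  kp <- as.integer(kp)
  if (is.na(kp) || kp < 1L)
    stop("`kp` must be a positive integer", call. = FALSE)
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    proteins <- Biostrings::readAAStringSet(proteins)
  }
  seqs <- as.character(proteins)
  if (length(seqs) == 0L)
    stop("no protein sequences in the training set", call. = FALSE)
  kmers <- cpp_peptide_kmers(unname(seqs), kp)
  structure(list(kp = kp, kmers = kmers,
                 n_source_proteins = length(seqs)),
            class = "peptide_set")
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set: %d distinct %d-mers from %d proteins\n",
              length(x$kmers), x$kp, x$n_source_proteins))
  invisible(x)
}

#' Serialize a peptide index to a plain-text file
#'
#' Versioned internal format so large training-set indices are built once and
#' reused: a header line with `kp` and the source-protein count, then one
#' kmer per line.
#'
#' @param x A `peptide_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_set <- function(x, path) {
  stopifnot(inherits(x, "peptide_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#corseqr-peptide-set\tv1\tkp=%d\tn_source_proteins=%d",
                     x$kp, x$n_source_proteins), con)
  writeLines(x$kmers, con)
  invisible(path)
}

#' @rdname write_peptide_set
#' @export
read_peptide_set <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#corseqr-peptide-set"))
    stop("not a corseqr peptide-set file: ", path, call. = FALSE)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  field <- function(key) {
    v <- hdr[startsWith(hdr, paste0(key, "="))]
    as.integer(sub(paste0(key, "="), "", v, fixed = TRUE))
  }
  structure(list(kp = field("kp"), kmers = lines[-1L],
                 n_source_proteins = field("n_source_proteins")),
            class = "peptide_set")
}
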