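# Independent brute-force oracles, written against base R / Biostrings and
# never sharing code with the implementation under test.

# All distinct kp-length windows over a set of proteins (step 1), dropping
# windows with any character outside the 20 standard amino acids.
oracle_peptide_kmers <- function(proteins, kp) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(0)
  for (p in toupper(proteins)) {
    n <- nchar(p)
    if (n < kp) next
    for (i in seq_len(n - kp + 1)) {
      w <- substr(p, i, i + kp - 1)
      if (all(strsplit(w, "")[[1]] %in% std)) out <- c(out, w)
    }
  }
  unique(out)
}

# Frame-aligned kmer enumeration: every substring of length k starting at
# offsets 0, 3, 6, ... (skipping non-ACGT windows), tabulated.
oracle_count_kmers <- function(orfs, k) {
  grab <- unlist(lapply(orfs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq(1L, n - k + 1L, by = 3L)
    w <- substring(s, starts, starts + k - 1L)
    w[!grepl("[^ACGT]", w)]
  }))
  if (length(grab) == 0L)
    return(stats::setNames(integer(0), character(0)))
  tab <- table(grab)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Triplet-slicing codon counter over sequences with length a multiple of 3.
oracle_count_codons <- function(kmers, weights = NULL) {
  if (is.null(weights)) weights <- rep(1L, length(kmers))
  counts <- numeric(0)
  for (i in seq_along(kmers)) {
    s <- kmers[i]
    if (grepl("[^ACGT]", s) || nchar(s) %% 3 != 0) next
    starts <- seq(1L, nchar(s), by = 3L)
    for (cd in substring(s, starts, starts + 2L)) {
      counts[cd] <- (if (is.na(counts[cd])) 0 else counts[cd]) + weights[i]
    }
  }
  counts[!names(counts) %in% c("TAA", "TAG", "TGA")]
}

# Biostrings-based translation (independent of the C++ genetic-code table).
# no.init.codon: never special-case CTG/TTG as initiator Met.
oracle_translate <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     no.init.codon = TRUE))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
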