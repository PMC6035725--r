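#' Sample reads from a FASTQ file up to a base budget
#'
#' Draws reads uniformly with replacement from the FASTQ until the
#' accumulated number of bases reaches `nob` (number of bases). The same
#' source read may therefore appear multiple times, and files smaller than
#' `nob` still yield a full-size sample. Quality strings are parsed but not
#' used. With replacement sampling means the final sample is more likely
#' populated by reads from the most abundant transcripts even for tiny
#' input files.
#'
#' @param fastq_path FASTQ file (plain or gzipped).
#' @param nob Number of bases to accumulate (default 2e7).
#' @param seed Integer seed; identical `(file, nob, seed)` gives an
#'   identical sample.
#' @return A `read_sample`: list with `read_id`, `sequence` (parallel
#'   character vectors), `total_bases`, `nob_target`, `seed`.
#' @export
sample_reads <- function(fastq_path, nob = corseq_defaults()$nob, seed = 1L) {
  nob <- as.numeric(nob)
  if (is.na(nob) || nob < 1)
    stop("`nob` must be >= 1", call. = FALSE)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq_path, format = "fastq"),
    error = function(e)
      stop("malformed or unreadable FASTQ '", fastq_path, "': ",
           conditionMessage(e), call. = FALSE))
  n <- length(reads)
  if (n == 0L) stop("FASTQ file is empty: ", fastq_path, call. = FALSE)
  w <- Biostrings::width(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  seqs <- as.character(reads)

  idx <- with_seed(seed, {
    drawn <- integer(0)
    total <- 0
    while (total < nob) {
      shortfall <- nob - total
      batch <- max(ceiling(shortfall / mean(w)), 1L)
      drawn <- c(drawn, sample.int(n, batch, replace = TRUE))
      total <- sum(w[drawn])
    }
    cum <- cumsum(w[drawn])
    drawn[seq_len(which(cum >= nob)[1L])]
  })

  structure(list(read_id = ids[idx], sequence = unname(seqs[idx]),
                 total_bases = sum(w[idx]), nob_target = nob,
                 seed = as.integer(seed)),
            class = "read_sample")
}

#' @export
print.read_sample <- function(x, ...) {
  cat(sprintf("read_sample: %d reads, %d bases (target %g, seed %d)\n",
              length(x$sequence), x$total_bases, x$nob_target, x$seed))
  invisible(x)
}

#' Locate the coding frame and orientation of reads via the peptide index
#'
#' Scans every offset `0..len - 3*kp` on the forward read, then every offset
#' on the reverse complement. A window qualifies if it is pure ACGT,
#' translates under the standard genetic code with no stop codon, and its
#' translation is a member of the index. The first qualifying window wins
#' (forward strand before reverse, lower offset first); its position and
#' orientation are taken as the read's coding frame.
#'
#' `find_frames()` is the vectorized form used by the pipeline;
#' `find_frame()` handles a single read and returns `NULL` on no match.
#'
#' @param reads Character vector of nucleotide reads.
#' @param read Single nucleotide read.
#' @param index A `peptide_set` from [build_peptide_set()].
#' @return `find_frames()`: data frame with one row per read, columns
#'   `orientation` (`"forward"`/`"reverse"`, NA if no match), `offset`
#'   (0-based on the oriented read) and `peptide`. `find_frame()`: a
#'   `frame_match` list (`orientation`, `offset`, `peptide`) or `NULL`.
#' @export
find_frames <- function(reads, index) {
  stopifnot(inherits(index, "peptide_set"))
  res <- cpp_find_frames(as.character(reads), index$kmers, index$kp)
  data.frame(orientation = c("forward", "reverse")[res$orientation],
             offset = res$offset, peptide = res$peptide,
             stringsAsFactors = FALSE)
}

#' @rdname find_frames
#' @export
find_frame <- function(read, index) {
  res <- find_frames(read, index)
  if (is.na(res$orientation[1L])) return(NULL)
  structure(list(orientation = res$orientation[1L],
                 offset = res$offset[1L], peptide = res$peptide[1L]),
            class = "frame_match")
}

#' Cut a read to its inferred coding frame (pseudo-ORF)
#'
#' Orients the read per the frame match (reverse complement for reverse
#' matches), trims `offset %% 3` bases from the 5' end so the matched window
#' sits on a codon boundary, and trims the 3' end so the length is a
#' multiple of 3. The pseudo-ORF spans the whole oriented read in the
#' matched frame, not just the matched window.
#'
#' @param read Nucleotide string the match was computed from.
#' @param match A `frame_match` from [find_frame()].
#' @return A `pseudo_orf`: list with `sequence` and `source_offset` (the
#'   5' trim applied on the oriented read).
#' @export
extract_pseudo_orf <- function(read, match) {
  oriented <- if (identical(match$orientation, "reverse"))
    cpp_revcomp(read) else toupper(read)
  lead <- match$offset %% 3L
  len <- nchar(oriented) - lead
  len <- len - (len %% 3L)
  seq <- substr(oriented, lead + 1L, lead + len)
  if (nchar(seq) < match$offset - lead + 3L * nchar(match$peptide))
    stop("pseudo-ORF shorter than the matched window: inconsistent match",
         call. = FALSE)
  structure(list(sequence = seq, source_offset = lead),
            class = "pseudo_orf")
}

#' @rdname extract_pseudo_orf
#' @param reads Character vector of reads.
#' @param frames Data frame from [find_frames()] over the same reads.
#' @return `extract_pseudo_orfs()`: character vector of pseudo-ORF
#'   sequences, one per matched read (unmatched reads are dropped).
#' @export
extract_pseudo_orfs <- function(reads, frames) {
  hit <- !is.na(frames$orientation)
  reads <- toupper(as.character(reads)[hit])
  rev <- frames$orientation[hit] == "reverse"
  reads[rev] <- cpp_revcomp(reads[rev])
  lead <- frames$offset[hit] %% 3L
  len <- nchar(reads) - lead
  len <- len - (len %% 3L)
  substr(reads, lead + 1L, lead + len)
}
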