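write_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path,
                              format = "fastq", qualities = q)
  path
}

test_that("read sampling accumulates with replacement to the base budget", {
  fq <- write_fastq(c(r1 = random_dna(100)))
  smp <- sample_reads(fq, nob = 250, seed = 9)
  expect_length(smp$sequence, 3)
  expect_equal(smp$total_bases, 300)

  set.seed(77)
  reads <- vapply(1:1000, function(i) random_dna(150), "")
  names(reads) <- sprintf("r%04d", 1:1000)
  fq2 <- write_fastq(reads)
  a <- sample_reads(fq2, nob = 15000, seed = 4)
  b <- sample_reads(fq2, nob = 15000, seed = 4)
  expect_length(a$sequence, 100)
  expect_identical(a$read_id, b$read_id)
  expect_identical(sort(a$sequence), sort(b$sequence))
  expect_gt(anyDuplicated(
    sample_reads(fq2, nob = 300000, seed = 4)$read_id), 0)
})

test_that("default base budget is 20 million", {
  expect_identical(corseq_defaults()$nob, 20000000L)
  expect_identical(formals(sample_reads)$nob, quote(corseq_defaults()$nob))
})

test_that("sampling rejects empty or missing input", {
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_error(sample_reads(empty, nob = 10), "empty")
  expect_error(sample_reads(tempfile(), nob = 10), "FASTQ")
  fq <- write_fastq(c(r1 = random_dna(50)))
  expect_error(sample_reads(fq, nob = 0), ">= 1")
})

test_that("frame search finds the first qualifying window, forward first", {
  idx <- build_peptide_set("KVL", kp = 3) # index = {"KVL"} only
  m <- find_frame("ATGAAAGTTCTGGCA", idx)
  expect_equal(m$orientation, "forward")
  expect_equal(m$offset, 3)
  expect_equal(m$peptide, "KVL")

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAAGTTCTGGCA")))
  m2 <- find_frame(rc, idx)
  expect_equal(m2$orientation, "reverse")
  expect_equal(m2$offset, 3)
  expect_equal(m2$peptide, "KVL")

  expect_null(find_frame("TTTTTTTTTTTTTTT", idx))
  expect_null(find_frame("ATGAAA", idx)) # shorter than the 3*kp window
})

test_that("matched windows translate to an index member with no stop", {
  set.seed(101)
  prots <- vapply(1:20, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                 replace = TRUE), collapse = ""), "")
  idx <- build_peptide_set(prots, kp = 5)
  reads <- vapply(1:200, function(i) random_dna(60), "")
  fr <- find_frames(reads, idx)
  hits <- which(!is.na(fr$orientation))
  for (i in hits) {
    oriented <- if (fr$orientation[i] == "reverse")
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(reads[i]))) else reads[i]
    win <- substr(oriented, fr$offset[i] + 1, fr$offset[i] + 15)
    expect_identical(oracle_translate(win), fr$peptide[i])
    expect_false(grepl("*", fr$peptide[i], fixed = TRUE))
    expect_true(fr$peptide[i] %in% idx$kmers)
  }
})

test_that("forward matches are preferred and earliest offsets win", {
  # index contains peptides readable at several positions; enumerate all
  # qualifying windows in R and check first-match semantics
  set.seed(55)
  prots <- vapply(1:10, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30,
                 replace = TRUE), collapse = ""), "")
  idx <- build_peptide_set(prots, kp = 3)
  reads <- vapply(1:100, function(i) random_dna(30), "")
  fr <- find_frames(reads, idx)
  qualifying <- function(s) {
    offs <- 0:(nchar(s) - 9)
    ok <- vapply(offs, function(o) {
      w <- substr(s, o + 1, o + 9)
      aa <- oracle_translate(w)
      !grepl("*", aa, fixed = TRUE) && aa %in% idx$kmers
    }, NA)
    offs[ok]
  }
  for (i in seq_along(reads)) {
    fwd <- qualifying(reads[i])
    rev <- qualifying(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(reads[i]))))
    if (length(fwd)) {
      expect_equal(fr$orientation[i], "forward")
      expect_equal(fr$offset[i], fwd[1])
    } else if (length(rev)) {
      expect_equal(fr$orientation[i], "reverse")
      expect_equal(fr$offset[i], rev[1])
    } else {
      expect_true(is.na(fr$orientation[i]))
    }
  }
})

test_that("match fraction grows monotonically with nested indices", {
  set.seed(19)
  prots <- vapply(1:30, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50,
                 replace = TRUE), collapse = ""), "")
  reads <- vapply(1:300, function(i) random_dna(45), "")
  full <- build_peptide_set(prots, kp = 4)
  fractions <- vapply(c(0.2, 0.6, 1), function(p) {
    sub <- full
    sub$kmers <- full$kmers[seq_len(floor(p * length(full$kmers)))]
    mean(!is.na(find_frames(reads, sub)$orientation))
  }, 1)
  expect_true(all(diff(fractions) >= 0))
})

test_that("pseudo-ORF extraction trims to the matched codon frame", {
  m <- structure(list(orientation = "forward", offset = 3L,
                      peptide = "KVL"), class = "frame_match")
  po <- extract_pseudo_orf("ATGAAAGTTCTGGCA", m)
  expect_equal(po$sequence, "ATGAAAGTTCTGGCA") # offset %% 3 == 0, 15 nt
  expect_equal(po$source_offset, 0L)

  read16 <- "TATGAAAGTTCTGGCA"
  m2 <- structure(list(orientation = "forward", offset = 4L,
                       peptide = "KVL"), class = "frame_match")
  po2 <- extract_pseudo_orf(read16, m2)
  expect_equal(po2$sequence, substr(read16, 2, 16))
  expect_equal(nchar(po2$sequence) %% 3, 0)

  rc_read <- "TGCCAGAACTTTCAT"
  m3 <- find_frame(rc_read, build_peptide_set("KVL", kp = 3))
  po3 <- extract_pseudo_orf(rc_read, m3)
  expect_equal(po3$sequence, "ATGAAAGTTCTGGCA")
})

test_that("emitted pseudo-ORFs reproduce the matched peptide in frame 0", {
  set.seed(7)
  prots <- vapply(1:15, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                 replace = TRUE), collapse = ""), "")
  idx <- build_peptide_set(prots, kp = 4)
  reads <- vapply(1:300, function(i) random_dna(55), "")
  fr <- find_frames(reads, idx)
  orfs <- extract_pseudo_orfs(reads, fr)
  hit <- which(!is.na(fr$orientation))
  expect_length(orfs, length(hit))
  for (j in seq_along(hit)) {
    orf <- orfs[j]
    expect_equal(nchar(orf) %% 3, 0)
    expect_gte(nchar(orf), 12)
    aa <- oracle_translate(orf)
    expect_match(aa, fr$peptide[hit[j]], fixed = TRUE)
    # peptide sits at the codon position implied by the trimmed offset
    off <- fr$offset[hit[j]]
    pos <- (off - off %% 3) / 3 + 1
    expect_identical(substr(aa, pos, pos + 3), fr$peptide[hit[j]])
  }
})
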