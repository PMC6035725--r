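test_that("codon counting slices kmers into in-frame triplets", {
  expect_identical(count_codons("ATGATGATG")[["ATG"]], 3)
  cc <- count_codons("GCTGCAGCT")
  expect_identical(cc[["GCT"]], 2)
  expect_identical(cc[["GCA"]], 1)
  fam_total <- sum(cc[c("GCT", "GCC", "GCA", "GCG")])
  expect_identical(fam_total, 3)
})

test_that("stop triplets are excluded from families; bad kmers skipped", {
  cc <- count_codons("ATGTAAGCT")
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(cc)))
  expect_identical(unname(attr(cc, "stop_counts")["TAA"]), 1)
  expect_warning(cc2 <- count_codons(c("ATGNNNATG", "GCTGCA")), "skipped")
  expect_identical(cc2[["GCT"]], 1)
  expect_identical(attr(cc2, "skipped"), 1L)
})

test_that("codon counts match the slicing oracle, weighted and not", {
  set.seed(41)
  for (rep in 1:30) {
    kmers <- vapply(seq_len(sample(10:50, 1)), function(i)
      random_dna(39), "")
    w <- sample(1:9, length(kmers), replace = TRUE)
    for (weights in list(NULL, w)) {
      got <- count_codons(kmers, weights)
      want <- oracle_count_codons(kmers, weights)
      got <- got[got > 0]
      expect_equal(got[order(names(got))], want[order(names(want))],
                   ignore_attr = TRUE)
      expect_identical(sort(names(got)), sort(names(want)))
    }
  }
})

test_that("the 2x2 test reproduces closed-form values", {
  res <- codon_test(90, 10, 50, 50)
  expect_equal(res$odds_ratio, 9)
  expect_equal(res$chi_square, 200 * (90 * 50 - 10 * 50)^2 /
                 (100 * 100 * 140 * 60))
  expect_equal(res$chi_square, 38.0952381, tolerance = 1e-6)

  flat <- codon_test(25, 25, 25, 25)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$chi_square, 0)
})

test_that("chi-square matches the uncorrected Pearson test to 1e-9", {
  set.seed(97)
  for (rep in 1:300) {
    tbl <- matrix(sample(1:500, 4, replace = TRUE), 2)
    res <- codon_test(tbl[1, 1], tbl[1, 2], tbl[2, 1], tbl[2, 2])
    ref <- suppressWarnings(chisq.test(tbl, correct = FALSE))
    expect_equal(res$chi_square, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$odds_ratio,
                 tbl[1, 1] * tbl[2, 2] / (tbl[1, 2] * tbl[2, 1]))
  }
})

test_that("zero cells keep the odds ratio finite, zero margins kill chi", {
  res <- codon_test(10, 0, 5, 5)
  expect_true(is.finite(res$odds_ratio))
  expect_equal(res$odds_ratio, (10.5 * 5.5) / (0.5 * 5.5))
  marg <- codon_test(0, 10, 0, 10) # codon margin a+c == 0
  expect_equal(marg$chi_square, 0)
  expect_error(codon_test(0, 0, 5, 5), "a\\+b")
  expect_error(codon_test(-1, 2, 3, 4), "nonnegative")
})

test_that("swapping the two groups inverts the odds ratio, preserves chi", {
  set.seed(15)
  for (rep in 1:50) {
    x <- sample(1:200, 4, replace = TRUE)
    fwd <- codon_test(x[1], x[2], x[3], x[4])
    swp <- codon_test(x[3], x[4], x[1], x[2])
    expect_equal(swp$odds_ratio, 1 / fwd$odds_ratio)
    expect_equal(swp$chi_square, fwd$chi_square)
  }
})

test_that("favoured calls follow the OR > 1 and chi > 3.84 rule", {
  # Ala high usage 90% GCT vs low 25%, large counts -> GCT favoured
  high <- c(GCT = 900, GCC = 40, GCA = 30, GCG = 30,
            AAA = 100, AAG = 100)
  low <- c(GCT = 250, GCC = 250, GCA = 250, GCG = 250,
           AAA = 100, AAG = 100)
  rep_ <- call_favoured(high, low)
  expect_true(rep_$favoured[rep_$codon == "GCT"])
  expect_false(any(rep_$favoured[rep_$codon %in% c("GCC", "GCA", "GCG")]))
  expect_false(any(rep_$favoured[rep_$codon %in% c("AAA", "AAG")]))

  same <- call_favoured(high, high)
  expect_length(favoured_codons(same), 0)
})

test_that("single-codon families and stops never enter the testable set", {
  high <- c(ATG = 500, TGG = 500, GCT = 100, GCC = 100, TAA = 9)
  low <- c(ATG = 500, TGG = 500, GCT = 100, GCC = 100)
  rep_ <- call_favoured(high, low)
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% rep_$codon))
  # every codon of every multi-codon family is present
  expect_equal(nrow(rep_), 59)
})

test_that("per-family counts are conserved in the report", {
  fix <- small_fixture()
  rep_ <- suppressMessages(run_pipeline(fix$paths$reads,
                                        fix$paths$proteins,
                                        nob = 1e6, seed = 3,
                                        quiet = TRUE))
  for (aa in unique(rep_$amino_acid)) {
    sub <- rep_[rep_$amino_acid == aa, ]
    expect_equal(sub$a + sub$b,
                 rep(sum(sub$a), nrow(sub)), ignore_attr = TRUE)
    expect_equal(sub$c + sub$d,
                 rep(sum(sub$c), nrow(sub)), ignore_attr = TRUE)
  }
})

test_that("swapping tails turns the favoured set into the avoided set", {
  set.seed(61)
  codons <- names(corseqr:::genetic_code_map())
  high <- stats::setNames(sample(50:500, length(codons)), codons)
  low <- stats::setNames(sample(50:500, length(codons)), codons)
  ab <- call_favoured(high, low)
  ba <- call_favoured(low, high)
  m <- merge(as.data.frame(ab), as.data.frame(ba), by = "codon")
  expect_equal(m$odds_ratio.x, 1 / m$odds_ratio.y)
  expect_equal(m$chi_square.x, m$chi_square.y)
  sig <- m$chi_square.x > 3.84
  expect_setequal(m$codon[sig & m$odds_ratio.x > 1],
                  m$codon[sig & m$odds_ratio.y < 1])
})

test_that("reports round-trip through the TSV format with metadata", {
  high <- c(GCT = 900, GCC = 40, GCA = 30, GCG = 30)
  low <- c(GCT = 250, GCC = 250, GCA = 250, GCG = 250)
  rep_ <- call_favoured(high, low, meta = list(kp = 11, seed = 42))
  path <- tempfile(fileext = ".tsv")
  write_codon_report(rep_, path)
  back <- read_codon_report(path)
  expect_equal(back$codon, rep_$codon)
  expect_equal(back$odds_ratio, rep_$odds_ratio)
  expect_equal(favoured_codons(back), favoured_codons(rep_))
  expect_equal(attr(back, "meta")$seed, "42")
})
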