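# Shared synthetic datasets, built once per test session.
#
# The validation fixture follows the package's stated study conditions:
# 500 genes, log-normal expression (sdlog 1.8, ~100x interdecile range),
# planted-codon mass 0.7 in the top expression decile, 200,000 reads of
# 100 nt at 0.5% substitution error, truth seed 1. The pipeline and CEM
# reports on it are cached alongside so several test files can assert
# different properties without recomputing.

.fixture_cache <- new.env(parent = emptyenv())

validation_fixture <- function() {
  if (!is.null(.fixture_cache$main)) return(.fixture_cache$main)
  truth <- synthetic_truth(seed = 1L)
  dir <- file.path(tempdir(), "corseqr-validation")
  paths <- write_synthetic_dataset(truth, dir)
  index <- build_peptide_set(paths$proteins)
  smp <- sample_reads(paths$reads, seed = 1L)
  frames <- find_frames(smp$sequence, index)
  orfs <- extract_pseudo_orfs(smp$sequence, frames)
  tab <- count_kmers(orfs)
  report <- suppressMessages(
    run_pipeline(paths$reads, paths$proteins, seed = 1L, quiet = TRUE))
  cem <- suppressMessages(cem_favoured(paths$cds, paths$abundance))
  .fixture_cache$main <- list(truth = truth, paths = paths, index = index,
                              orfs = orfs, kmer_table = tab,
                              report = report, cem = cem)
  .fixture_cache$main
}

# Small dataset for fast end-to-end unit tests (not the study conditions).
small_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  truth <- synthetic_truth(n_genes = 80L, n_reads = 20000L,
                           protein_length_range = c(60L, 150L), seed = 5L)
  dir <- file.path(tempdir(), "corseqr-small")
  paths <- write_synthetic_dataset(truth, dir)
  .fixture_cache$small <- list(truth = truth, paths = paths)
  .fixture_cache$small
}
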