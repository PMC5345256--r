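# Independent naive-scan oracle: every window compared to the recognition
# sequence by direct string equality (N windows can never match).
scan_sites_oracle <- function(seq, recognition) {
  L <- nchar(seq)
  r <- nchar(recognition)
  if (L < r) return(integer(0))
  windows <- substring(seq, 1:(L - r + 1), r:L)
  which(windows == recognition) - 1L
}

random_genome <- function(n, gc = 0.5, chrom = "c1") {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  setNames(paste(sample(names(probs), n, replace = TRUE, prob = probs),
                 collapse = ""), chrom)
}

# long-format methylation data for one CpG from per-group value vectors
meth_row <- function(values_by_group, cpg = "cpg1") {
  purrr::imap_dfr(values_by_group, function(v, g) {
    tibble::tibble(cpg = cpg, sample = sprintf("%s_%d", g, seq_along(v)),
                   group = g, percent = v)
  })
}

write_fasta_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# fixtures are expensive; build lazily once per test run
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- suppressMessages(
      make_fixture(file.path(tempdir(), "msdaflp-fixture-default"),
                   params = sim_params(seed = 20))
    )
  }
  .fixture_cache$default
}

noisefree_fixture <- function() {
  if (is.null(.fixture_cache$noisefree)) {
    .fixture_cache$noisefree <- suppressMessages(
      make_fixture(file.path(tempdir(), "msdaflp-fixture-noisefree"),
                   study_spec = synth_study_spec(noise_sd = 0, n_planted = 0,
                                                 seed = 2),
                   params = sim_params(noise_sigma = 0, size_jitter_sd = 0,
                                       detection_threshold = 0, seed = 21))
    )
  }
  .fixture_cache$noisefree
}

# database large enough to mirror a ~2000-CpG study
big_db <- function() {
  if (is.null(.fixture_cache$big_db)) {
    sg <- generate_genome(synth_genome_spec(n_chromosomes = 2,
                                            chrom_length = 8e5,
                                            sbfi_per_chrom = 800, seed = 31))
    .fixture_cache$big_db <- suppressMessages(build_fragment_db(sg$genome))
  }
  .fixture_cache$big_db
}
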