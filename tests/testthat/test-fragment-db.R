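test_that("forward fragment of the 22-mer example is reproduced exactly", {
  db <- build_fragment_db(c(c1 = "AACCTGCAGGTACGTACCGGTT"),
                          size_range = c(1, 500))
  expect_equal(nrow(db), 1L)
  expect_equal(db$orientation, "+")
  expect_equal(db$insert_start, 8L)
  expect_equal(db$insert_end, 17L)
  expect_equal(db$insert_length, 9L)
  expect_equal(substr("AACCTGCAGGTACGTACCGGTT", 9, 17), "GGTACGTAC")
  expect_equal(db$sel_primary, "TA")
  expect_equal(db$sel_secondary, "TA")  # reverse complement of "TA"
  expect_equal(db$cpg_pos, 18L)
})

test_that("reverse fragment keeps the CGG remnant and the monitored CpG", {
  db <- build_fragment_db(c(c1 = "CCGGAAACCTGCAGGAA"), size_range = c(1, 500))
  expect_equal(nrow(db), 1L)
  expect_equal(db$orientation, "-")
  expect_equal(db$insert_start, 1L)
  expect_equal(db$insert_end, 9L)
  expect_equal(db$insert_length, 8L)
  expect_equal(db$cpg_pos, 2L)
  expect_equal(db$sel_secondary, "AA")
  expect_equal(db$sel_primary, "TT")  # reverse complement of "AA"
})

test_that("an SbfI site with no CCGG anywhere yields no fragments", {
  db <- build_fragment_db(c(c1 = "AACCTGCAGGTATATATATT"), size_range = c(1, 500))
  expect_equal(nrow(db), 0L)
})

test_that("inserts too short for both selective dinucleotides are excluded", {
  # CCGG right after the SbfI cut: insert length 3 < 4
  g <- c(c1 = "AACCTGCAGGCCGGTTTTTT")
  expect_message(db <- build_fragment_db(g, size_range = c(1, 500)),
                 "selective")
  expect_equal(nrow(db), 0L)
  fr <- tibble::tibble(chrom = "c1", orientation = "+", insert_start = 8L,
                       insert_end = 11L, cpg_pos = 12L)
  expect_warning(res <- selective_bases(fr, g), "too short")
  expect_true(is.na(res$sel_primary) || is.na(res$sel_secondary))
})

test_that("selective bases recomputed standalone match the builder", {
  fx <- default_fixture()
  res <- selective_bases(fx$db, fx$genome$genome)
  expect_equal(res$sel_primary, fx$db$sel_primary)
  expect_equal(res$sel_secondary, fx$db$sel_secondary)
})

test_that("builder output is identical to the brute-force reference digest", {
  for (seed in 1:30) {
    sg <- generate_genome(synth_genome_spec(n_chromosomes = 1,
                                            chrom_length = 20000,
                                            sbfi_per_chrom = 8,
                                            ccgg_per_kb = 3, seed = seed))
    fast <- suppressMessages(build_fragment_db(sg$genome))
    slow <- build_fragment_db_reference(sg$genome)
    expect_equal(as.data.frame(tibble::as_tibble(fast)),
                 as.data.frame(slow), ignore_attr = TRUE)
  }
})

test_that("no insert contains an internal CCGG and counts are bounded", {
  fx <- default_fixture()
  db <- fx$db
  genome <- fx$genome$genome
  for (i in seq_len(nrow(db))) {
    insert <- substr(genome[[db$chrom[i]]], db$insert_start[i] + 1L,
                     db$insert_end[i])
    inner <- substr(insert, 2, nchar(insert) - 1)
    expect_false(grepl("CCGG", inner, fixed = TRUE))
  }
  n_sbfi <- nrow(fx$genome$sbfi_sites)
  expect_lte(nrow(db), 2L * n_sbfi)
  # monitored CpGs are realized CCGG sites of the generated sequence
  expect_true(all((db$cpg_pos - 2L) %in% fx$genome$ccgg_sites$site_start))
})

test_that("uniqueness is keyed by selective subset at 1-nt resolution", {
  mk <- function(sp, ss, dl) {
    tibble::tibble(chrom = "c1", orientation = "+",
                   insert_start = seq_along(dl) * 1000L,
                   insert_end = seq_along(dl) * 1000L + dl,
                   insert_length = dl, display_length = dl,
                   sel_primary = sp, sel_secondary = ss,
                   cpg_pos = seq_along(dl) * 1000L + 2L)
  }
  one <- uniqueness_report(mk("AA", "CC", c(100L, 150L, 150L, 200L)))
  expect_equal(one$n_single_peak, 2L)
  expect_equal(one$fraction_single, 0.5)

  distinct_lengths <- uniqueness_report(mk("AA", "CC", c(100L, 150L, 200L)))
  expect_equal(distinct_lengths$fraction_single, 1)

  same_subset <- uniqueness_report(
    dplyr::bind_rows(mk("AA", "CC", c(100L, 100L)), mk("GG", "TT", c(100L, 100L))))
  expect_equal(same_subset$fraction_single, 0)

  split_subsets <- uniqueness_report(
    dplyr::bind_rows(mk("AA", "CC", 100L), mk("GG", "TT", 100L)))
  expect_equal(split_subsets$fraction_single, 1)
})

test_that("uniqueness totals are invariant to record order", {
  fx <- default_fixture()
  rep1 <- uniqueness_report(fx$db)
  shuffled <- tibble::as_tibble(fx$db)[sample(nrow(fx$db)), ]
  rep2 <- uniqueness_report(shuffled)
  expect_equal(rep1$total_fragments, rep2$total_fragments)
  expect_equal(rep1$n_single_peak, rep2$n_single_peak)
  expect_equal(rep1$fraction_single, rep2$fraction_single)
  expect_equal(dplyr::arrange(tidy(rep1), sel_primary, sel_secondary),
               dplyr::arrange(tidy(rep2), sel_primary, sel_secondary))
})

test_that("locus queries round-trip every fragment and order candidates", {
  fx <- default_fixture()
  db <- fx$db
  idx <- seq(1, nrow(db), by = 7)
  for (i in idx) {
    hits <- query_loci(db, db$sel_primary[i], db$sel_secondary[i],
                       db$display_length[i], tolerance = 0)
    expect_true(any(hits$chrom == db$chrom[i] &
                      hits$insert_start == db$insert_start[i] &
                      hits$orientation == db$orientation[i]))
  }
  expect_equal(nrow(query_loci(db, "AA", "AA", 10000, tolerance = 0)), 0L)
  expect_error(query_loci(db, "A", "AA", 100), "length-2")
})

test_that("nearest candidate is returned first", {
  db <- structure(
    tibble::tibble(chrom = c("c1", "c1"), orientation = c("+", "+"),
                   insert_start = c(100L, 900L), insert_end = c(300L, 1101L),
                   insert_length = c(200L, 201L), display_length = c(200L, 201L),
                   sel_primary = "AA", sel_secondary = "CC",
                   cpg_pos = c(302L, 1102L)),
    class = c("fragment_db", class(tibble::tibble())))
  hits <- query_loci(db, "AA", "CC", 200.4, tolerance = 1)
  expect_equal(hits$display_length, c(200L, 201L))
})

test_that("intragenic fraction counts monitored CpGs inside intervals", {
  db <- tibble::tibble(chrom = rep("c1", 4), cpg_pos = c(10L, 20L, 30L, 40L))
  genes <- tibble::tibble(chrom = "c1", start = c(5L, 25L), end = c(22L, 35L))
  res <- intragenic_fraction(db, genes)
  expect_equal(res$n_inside, 3L)
  expect_equal(res$fraction, 0.75)
  expect_equal(intragenic_fraction(db, genes[0, ])$fraction, 0)
  all_in <- intragenic_fraction(db, tibble::tibble(chrom = "c1", start = 0L,
                                                   end = 100L))
  expect_equal(all_in$fraction, 1)
})

test_that("database TSV serialization round-trips records and metadata", {
  fx <- default_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_db(fx$db, path)
  db2 <- read_fragment_db(path)
  expect_equal(as.data.frame(tibble::as_tibble(db2)),
               as.data.frame(tibble::as_tibble(fx$db)))
  expect_equal(attr(db2, "size_range"), attr(fx$db, "size_range"))
  expect_equal(attr(db2, "primary"), attr(fx$db, "primary"))
  expect_equal(attr(db2, "n_candidates"), attr(fx$db, "n_candidates"))
})
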