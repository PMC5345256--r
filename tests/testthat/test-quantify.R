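chart_row <- function(sample, size, height, sp = "AA", ss = "CC") {
  tibble::tibble(sample = sample, sel_primary = sp, sel_secondary = ss,
                 size = size, height = height)
}

test_that("peak matching bins by gap-split single linkage", {
  ch <- dplyr::bind_rows(chart_row("s1", 100.1, 500), chart_row("s2", 100.3, 700))
  tab <- match_peaks(ch, tolerance = 0.5)
  expect_equal(length(unique(tab$bin)), 1L)
  expect_equal(unique(tab$size), 100.2)

  ch2 <- dplyr::bind_rows(chart_row("s1", 100.0, 500), chart_row("s2", 101.0, 700))
  expect_equal(length(unique(match_peaks(ch2, 0.5)$bin)), 2L)
})

test_that("absent samples are filled with zero and flagged", {
  ch <- dplyr::bind_rows(chart_row("s1", 100, 500), chart_row("s2", 100.2, 700),
                         chart_row("s2", 200, 900))
  tab <- match_peaks(ch, 0.5)
  missing_row <- tab[tab$sample == "s1" & tab$size == 200, ]
  expect_equal(missing_row$height, 0)
  expect_true(missing_row$absent)
})

test_that("duplicate peaks from one sample keep the taller with a warning", {
  ch <- dplyr::bind_rows(chart_row("s1", 100.0, 500), chart_row("s1", 100.2, 800))
  expect_warning(tab <- match_peaks(ch, 0.5), "taller")
  expect_equal(tab$height, 800)
})

test_that("mixed selective pairs are refused", {
  ch <- dplyr::bind_rows(chart_row("s1", 100, 500, sp = "AA"),
                         chart_row("s1", 100, 500, sp = "GG"))
  expect_error(match_peaks(ch), "selective-primer pair")
})

test_that("signal ratios divide by the reference and drop dead bins", {
  ch <- dplyr::bind_rows(chart_row("s1", 100, 500), chart_row("ref", 100.1, 1000),
                         chart_row("s1", 200, 300))
  tab <- match_peaks(ch, 0.5)
  expect_warning(sr <- signal_ratio(tab, "ref"), "reference")
  expect_equal(sr$sr[sr$size < 150], 0.5)
  expect_false(any(sr$size > 150))  # bin without reference dropped
  expect_error(signal_ratio(tab, "nope"), "not in table")
})

test_that("a chart ratioed against itself gives SR 1 everywhere", {
  fx <- default_fixture()
  pair <- fx$sel_pairs[1, ]
  ref <- fx$charts |>
    dplyr::filter(sample == "SssI_reference",
                  sel_primary == pair$sel_primary,
                  sel_secondary == pair$sel_secondary)
  twice <- dplyr::bind_rows(ref, dplyr::mutate(ref, sample = "copy"))
  sr <- signal_ratio(match_peaks(twice), "SssI_reference")
  expect_equal(sr$sr, rep(1, nrow(sr)))
})

test_that("Hill fitting recovers known saturating parameters", {
  sr <- seq(0.05, 1.2, length.out = 11)
  pts <- tibble::tibble(sr = sr, percent = 100 * sr^2 / (0.5^2 + sr^2))
  fit <- fit_hill(pts)
  expect_lt(abs(fit$h - 2), 1e-4)
  expect_lt(abs(fit$K - 0.5), 1e-4)
  expect_lt(abs(fit$emax - 100), 0.05)

  half <- fit_hill(tibble::tibble(sr = sr, percent = 100 * sr / (1 + sr)))
  expect_lt(abs(half$h - 1), 1e-3)
  expect_lt(abs(half$K - 1), 1e-2)
})

test_that("Hill fitting is exact on a saturation-free linear response", {
  pts <- tibble::tibble(sr = seq(0.05, 1, length.out = 11),
                        percent = 100 * seq(0.05, 1, length.out = 11))
  fit <- fit_hill(pts)
  expect_lt(max(abs(hill_percent(fit, pts$sr) - pts$percent)), 1e-6)
  expect_false(is.finite(fit$emax))  # power-law boundary
  constrained <- fit_hill(pts, emax = 100)
  expect_gt(constrained$rmse, 1)  # fixed asymptote cannot represent a line
})

test_that("Hill fitting validates its inputs", {
  expect_error(fit_hill(tibble::tibble(sr = c(0.1, 0.5), percent = c(10, 50))),
               "at least 3")
  expect_error(fit_hill(tibble::tibble(sr = rep(0.5, 4), percent = 1:4 * 10)),
               "distinct")
})

test_that("calibrated percents are monotone, bounded and anchored", {
  sr <- seq(0.05, 1.2, length.out = 11)
  fit <- fit_hill(tibble::tibble(sr = sr, percent = 100 * sr^2 / (0.5^2 + sr^2)))
  grid <- seq(0, 5, length.out = 400)
  vals <- hill_percent(fit, grid)
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= 0 & vals <= 100))
  expect_equal(hill_percent(fit, 0), 0)
  expect_equal(hill_percent(fit, fit$K), fit$emax / 2, tolerance = 1e-6)
  manual <- list(h = 1, K = 1)
  expect_equal(hill_percent(manual, 1), 50)
  expect_gt(hill_percent(manual, 1e4), 99.9)
  expect_error(hill_percent(manual, -0.1), "non-negative")
})

test_that("calibration recovery from noisy points stays within 5 points RMSE", {
  true_fit <- function(x) 100 * x^2 / (0.5^2 + x^2)
  sr <- seq(0.05, 1.2, length.out = 11)
  true_percent <- true_fit(sr)
  rmses <- withr::with_seed(77, replicate(20, {
    noisy <- sr * exp(rnorm(11, 0, 0.05))
    fit <- fit_hill(tibble::tibble(sr = noisy, percent = true_percent))
    grid <- seq(0.05, 1.2, length.out = 100)
    sqrt(mean((hill_percent(fit, grid) - true_fit(grid))^2))
  }))
  expect_lt(mean(rmses), 5)
  expect_gt(mean(rmses), 0.01)  # guards against accidentally noiseless points
})

test_that("MSRE percent clamps and validates", {
  expect_equal(msre_percent(list(copies_hpaii = 50, copies_stui = 100)), 50)
  expect_equal(msre_percent(0, 100), 0)
  expect_warning(res <- msre_percent(103, 100), "clamped")
  expect_equal(res, 100)
  expect_error(msre_percent(10, 0), "copies_stui")
})

test_that("quantification composes SR and calibration over a table", {
  ch <- dplyr::bind_rows(chart_row("s1", 100, 500), chart_row("ref", 100.1, 1000))
  fit <- fit_hill(tibble::tibble(sr = seq(0.05, 1, length.out = 11),
                                 percent = 100 * seq(0.05, 1, length.out = 11)))
  out <- charts_to_percent(match_peaks(ch), "ref", fit)
  expect_equal(out$percent, 50, tolerance = 1e-6)
  # reference against itself lands at hill_percent(1)
  ch2 <- dplyr::bind_rows(chart_row("copy", 100, 1000), chart_row("ref", 100.1, 1000))
  out2 <- charts_to_percent(match_peaks(ch2), "ref", fit)
  expect_equal(out2$percent, hill_percent(fit, 1), tolerance = 1e-9)
})

test_that("locus annotation joins candidate loci onto quantified bins", {
  fx <- noisefree_fixture()
  pair <- fx$sel_pairs[1, ]
  sub <- fx$charts |>
    dplyr::filter(sel_primary == pair$sel_primary,
                  sel_secondary == pair$sel_secondary)
  fit <- fit_hill(fx$calibration)
  out <- charts_to_percent(match_peaks(sub), calibration = fit, db = fx$db)
  expect_true(all(out$n_candidates >= 1))
  expect_true(all((out$cpg_pos - 2L) %in% fx$genome$ccgg_sites$site_start))
})
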