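#' Match peaks across charts into bins
#'
#' Bins peaks of several charts (all from one selective-primer pair) by size
#' using single-linkage clustering in one dimension: sorted sizes are split
#' wherever consecutive peaks are more than `tolerance` nt apart. When one
#' sample contributes two peaks to a bin the taller is kept (with a warning).
#' Samples absent from a bin get height 0 and an `absent` flag, so every bin
#' carries one row per sample.
#'
#' @param charts One or more `peak_chart` tibbles row-bound together.
#' @param tolerance Maximum size gap (nt) joining neighbouring peaks into one
#'   bin. The 0.5 nt default reflects capillary sizing precision.
#' @return Tibble of class `peak_table`: `bin`, `size` (mean of member
#'   sizes), `sample`, `height`, `absent`; attributes `sel_primary`,
#'   `sel_secondary`, `tolerance`, `samples`.
#' @export
match_peaks <- function(charts, tolerance = 0.5) {
  stopifnot(tolerance >= 0)
  charts <- as_tibble(charts)
  stop_if_missing_cols(charts, c("sample", "sel_primary", "sel_secondary",
                                 "size", "height"), "peak charts")
  pairs <- distinct(charts, .data$sel_primary, .data$sel_secondary)
  if (nrow(pairs) != 1) {
    abort("all charts in one peak table must share a selective-primer pair")
  }
  samples <- unique(charts$sample)
  charts <- arrange(charts, .data$size)
  charts$bin <- cumsum(c(1L, as.integer(diff(charts$size) > tolerance)))

  dup <- charts |>
    group_by(.data$bin, .data$sample) |>
    filter(n() > 1L)
  if (nrow(dup) > 0) {
    warn(sprintf("%d sample/bin pair(s) contributed multiple peaks; keeping the taller",
                 nrow(distinct(dup, .data$bin, .data$sample))))
  }
  binned <- charts |>
    group_by(.data$bin, .data$sample) |>
    arrange(dplyr::desc(.data$height), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup()
  rep_size <- binned |>
    group_by(.data$bin) |>
    summarise(size = mean(.data$size), .groups = "drop")
  full <- tidyr::expand_grid(bin = rep_size$bin, sample = samples) |>
    left_join(rep_size, by = "bin") |>
    left_join(binned |> select("bin", "sample", "height"),
              by = c("bin", "sample")) |>
    mutate(absent = is.na(.data$height),
           height = dplyr::coalesce(.data$height, 0)) |>
    arrange(.data$bin, .data$sample)
  structure(full, class = c("peak_table", class(tibble())),
            sel_primary = pairs$sel_primary[1],
            sel_secondary = pairs$sel_secondary[1],
            tolerance = tolerance, samples = samples)
}

#' Signal ratios against the fully methylated reference
#'
#' Divides each sample's peak height by the height of the SssI (fully
#' methylated) reference in the same bin. Bins in which the reference is
#' absent or non-positive cannot be ratioed and are dropped with a warning.
#' Raw SR values are reported unclamped (values above 1 are diagnostic);
#' clamping happens only at the percent stage.
#'
#' @param table A [match_peaks()] result.
#' @param reference_sample Sample label of the reference chart.
#' @return Tibble of class `sr_table`: `bin`, `size`, `sample`, `height`,
#'   `absent`, `ref_height`, `sr`, reference rows excluded.
#' @export
signal_ratio <- function(table, reference_sample = "SssI_reference") {
  stop_if_missing_cols(table, c("bin", "size", "sample", "height"), "peak table")
  if (!reference_sample %in% table$sample) {
    abort(sprintf("reference sample '%s' not in table", reference_sample))
  }
  ref <- table |>
    filter(.data$sample == .env$reference_sample) |>
    select("bin", ref_height = "height")
  out <- table |>
    filter(.data$sample != .env$reference_sample) |>
    left_join(ref, by = "bin")
  dropped <- unique(out$bin[out$ref_height <= 0])
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d bin(s) with no reference signal", length(dropped)))
    out <- out[!out$bin %in% dropped, ]
  }
  out$sr <- out$height / out$ref_height
  structure(out, class = c("sr_table", class(tibble())),
            sel_primary = attr(table, "sel_primary"),
            sel_secondary = attr(table, "sel_secondary"),
            reference_sample = reference_sample)
}

hill_predict <- function(h, S, c0, sr) {
  # compactified Hill response: M = S * sr^h / (1 + (c0 * sr)^h);
  # c0 = 1/K, so c0 = 0 is the saturation-free power-law/linear limit
  S * sr^h / (1 + (c0 * sr)^h)
}

#' Fit the Hill calibration mapping signal ratio to percent methylation
#'
#' Least-squares fit of the Hill response
#' \deqn{M(SR) = E_{max} SR^h / (K^h + SR^h)}
#' to calibration points pairing a signal ratio with an independently
#' measured (MSRE-PCR) percent methylation. The curve is fitted in the
#' compactified parameterization \eqn{M = S\,SR^h / (1 + (c\,SR)^h)} with
#' \eqn{c = 1/K \ge 0} and amplitude \eqn{S = E_{max} c^h} free, whose
#' \eqn{c = 0} boundary is the saturation-free power-law limit (containing
#' the linear response \eqn{M = 100\,SR} at \eqn{h = 1}). This matters: a
#' detector with no PCR saturation is linear in SR, and that response is not
#' representable with a fixed asymptote. Optimization is multi-start
#' (Hill coefficients 0.5, 1, 2 and 4 around `K = median(SR)`, plus a
#' log-log regression start on the power-law boundary); the best final
#' objective is kept. Set `emax = 100` to constrain the classical
#' two-parameter fit. Predictions are clamped to `[0, 100]` by
#' [hill_percent()].
#'
#' @param points Tibble with columns `sr` and `percent` (a `msre_percent`
#'   column is accepted as the percent). At least 3 points with distinct SR.
#' @param emax `NULL` (free amplitude, default) or a fixed asymptote.
#' @return Object of class `hill_fit`: parameters `h`, `K`, `emax` (possibly
#'   `Inf` on the power-law boundary), initial slope-scale `S`, the points,
#'   fitted values, residuals and `rmse`.
#' @export
fit_hill <- function(points, emax = NULL) {
  points <- as_tibble(points)
  if (!"percent" %in% names(points) && "msre_percent" %in% names(points)) {
    points$percent <- points$msre_percent
  }
  stop_if_missing_cols(points, c("sr", "percent"), "calibration points")
  points <- points[complete.cases(points[, c("sr", "percent")]), ]
  if (nrow(points) < 3) abort("need at least 3 calibration points")
  if (length(unique(points$sr)) < 3) {
    abort("calibration points must have at least 3 distinct SR values")
  }
  if (any(points$sr < 0)) abort("SR must be non-negative")
  if (any(points$percent < 0 | points$percent > 100)) {
    abort("percent must lie in [0, 100]")
  }
  x <- points$sr
  y <- points$percent

  if (is.null(emax)) {
    obj <- function(par) {
      pred <- hill_predict(exp(par[1]), exp(par[2]), par[3], x)
      val <- sum((y - pred)^2)
      if (!is.finite(val)) 1e300 else val  # overflow guard for extreme h
    }
    k0 <- max(median(x), .Machine$double.eps)
    starts <- lapply(c(0.5, 1, 2, 4), function(h0) {
      c(log(h0), log(100 * (1 / k0)^h0), 1 / k0)
    })
    # power-law boundary start from log-log regression (positive points only)
    pos <- x > 0 & y > 0
    if (sum(pos) >= 2) {
      cf <- coef(lm(log(y[pos]) ~ log(x[pos])))
      starts <- c(starts, list(c(log(max(cf[2], 1e-3)), cf[1], 0)))
    }
    fits <- lapply(starts, function(p0) {
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(log(1e-2), -50, 0), upper = c(log(50), 50, 1e6),
            control = list(maxit = 2000, factr = 1e3))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    best <- optim(best$par, obj, method = "L-BFGS-B",
                  lower = c(log(1e-2), -50, 0), upper = c(log(50), 50, 1e6),
                  control = list(maxit = 2000, factr = 1))
    par <- unname(best$par)
    h <- exp(par[1]); S <- exp(par[2]); c0 <- par[3]
  } else {
    stopifnot(emax > 0)
    obj <- function(par) {
      hh <- exp(par[1]); K <- exp(par[2])
      sum((y - emax * x^hh / (K^hh + x^hh))^2)
    }
    k0 <- max(median(x), .Machine$double.eps)
    fits <- lapply(c(0.5, 1, 2, 4), function(h0) {
      optim(c(log(h0), log(k0)), obj, method = "BFGS",
            control = list(maxit = 2000, reltol = 1e-14))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    h <- exp(best$par[1]); K <- exp(best$par[2])
    c0 <- 1 / K; S <- emax * c0^h
  }

  fitted <- hill_predict(h, S, c0, x)
  structure(
    list(
      h = h, S = S, c = c0,
      K = if (c0 > 0) 1 / c0 else Inf,
      emax = if (c0 > 0) S / c0^h else Inf,
      emax_fixed = !is.null(emax),
      points = points, fitted = fitted, residuals = y - fitted,
      sse = sum((y - fitted)^2),
      rmse = sqrt(mean((y - fitted)^2)),
      n = nrow(points)
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill calibration (SR -> percent methylation)\n")
  if (is.finite(x$emax)) {
    cat(sprintf("  h = %.4g, K = %.4g, Emax = %.4g\n", x$h, x$K, x$emax))
  } else {
    cat(sprintf("  power-law limit (no saturation): M = %.4g * SR^%.4g\n",
                x$S, x$h))
  }
  cat(sprintf("  fit on %d points, residual RMSE %.3g percent\n", x$n, x$rmse))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("h", "K", "emax", "S"),
         estimate = c(x$h, x$K, x$emax, x$S))
}

#' @importFrom generics glance
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(h = x$h, K = x$K, emax = x$emax, rmse = x$rmse, n = x$n,
         saturating = is.finite(x$emax))
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  sr <- if (is.null(newdata)) object$points$sr
        else if (is.numeric(newdata)) newdata else newdata$sr
  hill_percent(object, sr)
}

#' Convert signal ratios to percent methylation
#'
#' Applies a fitted (or manually specified) Hill calibration and clamps the
#' result to `[0, 100]`; SR 0 maps to 0 and, for a saturating calibration,
#' `hill_percent(fit, K)` is exactly `Emax / 2`.
#'
#' @param calibration A [fit_hill()] object, or a list with `h` and `K`
#'   (optional `emax`, default 100).
#' @param sr Non-negative signal ratios.
#' @return Percent methylation values in `[0, 100]`.
#' @export
hill_percent <- function(calibration, sr) {
  if (any(sr < 0, na.rm = TRUE)) abort("SR must be non-negative")
  if (inherits(calibration, "hill_fit")) {
    raw <- hill_predict(calibration$h, calibration$S, calibration$c, sr)
  } else {
    h <- calibration$h; K <- calibration$K
    emax <- calibration$emax %||% 100
    stopifnot(h > 0, K > 0)
    raw <- emax * sr^h / (K^h + sr^h)
  }
  raw[sr == 0] <- 0
  clamp(raw, 0, 100)
}

#' Percent methylation from an MSRE-PCR measurement
#'
#' `100 * copies_hpaii / copies_stui`, clamped to `[0, 100]` with a warning
#' when the raw ratio exceeds 1 (qPCR noise can push the HpaII aliquot above
#' the control).
#'
#' @param measurement Tibble/list with `copies_hpaii` and `copies_stui`, or a
#'   numeric vector of HpaII copies when `copies_stui` is given separately.
#' @param copies_stui Optional control-digest copy numbers.
#' @return Percent methylation values.
#' @export
msre_percent <- function(measurement, copies_stui = NULL) {
  if (is.null(copies_stui)) {
    hp <- measurement$copies_hpaii
    st <- measurement$copies_stui
  } else {
    hp <- as.numeric(measurement)
    st <- as.numeric(copies_stui)
  }
  if (any(st <= 0)) abort("copies_stui must be > 0")
  raw <- 100 * hp / st
  if (any(raw > 100)) {
    warn(sprintf("%d measurement(s) exceeded 100%%; clamped", sum(raw > 100)))
  }
  clamp(raw, 0, 100)
}

#' Full quantification: peak table to percent methylation
#'
#' Composes [signal_ratio()] and [hill_percent()] over every bin and sample.
#' When a fragment database is supplied, each bin is annotated with its
#' candidate loci via [query_loci()] (nearest candidate's coordinates plus
#' the candidate count).
#'
#' @param table A [match_peaks()] result (or raw charts, which are matched
#'   with `match_tolerance`).
#' @param reference_sample Label of the fully methylated reference chart.
#' @param calibration A [fit_hill()] object.
#' @param db Optional [build_fragment_db()] result for locus annotation.
#' @param tolerance Size tolerance (nt) for locus queries.
#' @param match_tolerance Binning tolerance if `table` is raw charts.
#' @return Tibble: `bin`, `size`, `sample`, `sr`, `percent` (+ `chrom`,
#'   `cpg_pos`, `n_candidates` when `db` is given).
#' @export
charts_to_percent <- function(table, reference_sample = "SssI_reference",
                              calibration, db = NULL, tolerance = 1,
                              match_tolerance = 0.5) {
  if (!inherits(table, "peak_table")) table <- match_peaks(table, match_tolerance)
  srt <- signal_ratio(table, reference_sample)
  out <- as_tibble(srt) |>
    mutate(percent = hill_percent(calibration, .data$sr)) |>
    select("bin", "size", "sample", "sr", "percent")
  if (!is.null(db)) {
    sel_p <- attr(srt, "sel_primary")
    sel_s <- attr(srt, "sel_secondary")
    ann <- distinct(out, .data$bin, .data$size) |>
      mutate(purrr::map_dfr(.data$size, function(sz) {
        cand <- query_loci(db, sel_p, sel_s, sz, tolerance)
        tibble(chrom = if (nrow(cand)) cand$chrom[1] else NA_character_,
               cpg_pos = if (nrow(cand)) cand$cpg_pos[1] else NA_integer_,
               n_candidates = nrow(cand))
      }))
    out <- left_join(out, ann, by = c("bin", "size"))
  }
  out
}

#' Read / write calibration points
#'
#' TSV with columns `locus`, `sr`, `msre_percent`, the format produced by
#' [make_fixture()].
#'
#' @param points Calibration tibble.
#' @param path File path.
#' @return `path` invisibly; the reader returns a tibble.
#' @export
write_calibration <- function(points, path) {
  readr::write_tsv(as_tibble(points), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}

#' Quantify a whole study of peak charts
#'
#' Splits a collection of charts by selective-primer pair, bins each pair
#' with [match_peaks()], and converts every bin to percent methylation with
#' [charts_to_percent()], concatenating the results. With a fragment
#' database, bins are annotated with their predicted locus.
#'
#' @param charts Row-bound `peak_chart` tibbles covering one or more
#'   selective pairs (e.g. the `charts.csv` of a fixture).
#' @param calibration A [fit_hill()] object.
#' @param db Optional [build_fragment_db()] result for locus annotation.
#' @param reference_sample Label of the fully methylated reference chart.
#' @param match_tolerance Binning tolerance in nt.
#' @param query_tolerance Locus-query size tolerance in nt.
#' @return Tibble: `sel_primary`, `sel_secondary`, `bin`, `size`, `sample`,
#'   `sr`, `percent` (+ locus columns when `db` is given).
#' @export
study_percent_matrix <- function(charts, calibration, db = NULL,
                                 reference_sample = "SssI_reference",
                                 match_tolerance = 0.5, query_tolerance = 1) {
  charts <- as_tibble(charts)
  stop_if_missing_cols(charts, c("sample", "sel_primary", "sel_secondary",
                                 "size", "height"), "peak charts")
  keys <- distinct(charts, .data$sel_primary, .data$sel_secondary)
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    sub <- charts |>
      filter(.data$sel_primary == keys$sel_primary[i],
             .data$sel_secondary == keys$sel_secondary[i])
    if (!reference_sample %in% sub$sample) return(NULL)
    tab <- match_peaks(sub, match_tolerance)
    charts_to_percent(tab, reference_sample, calibration, db = db,
                      tolerance = query_tolerance) |>
      mutate(sel_primary = keys$sel_primary[i],
             sel_secondary = keys$sel_secondary[i], .before = 1)
  })
}
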