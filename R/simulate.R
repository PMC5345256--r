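#' Simulation parameters for the MSD-AFLP library chemistry
#'
#' Bundles the knobs of the forward simulator. Digestion completenesses are
#' fractions in `[0, 1]`; with all three at 1 (the default, matching the
#' vendor guarantee that CpG methylation blocks HpaII completely and that
#' digestion runs to completion) a fragment's expected abundance equals the
#' methylation level of its monitored CpG. Intensity noise is multiplicative
#' log-normal with standard deviation `noise_sigma` on the log scale, the
#' regime in which most replicate peak pairs fall within a 1.1-fold band.
#'
#' @param eff_hpaii Completeness of HpaII digestion of unmethylated sites.
#' @param eff_primary,eff_mspi Digestion completeness of the primary enzyme
#'   and MspI.
#' @param gain Fluorescence units (RFU) per unit expected abundance.
#' @param noise_sigma SD of the log-normal multiplicative intensity noise.
#' @param size_jitter_sd SD (nt) of Gaussian sizing jitter on reported peak
#'   positions.
#' @param detection_threshold Minimum reported peak height in RFU; weaker
#'   peaks are not called (typical capillary peak-calling floor).
#' @param seed Integer seed making simulated charts reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(eff_hpaii = 1, eff_primary = 1, eff_mspi = 1,
                       gain = 1000, noise_sigma = 0.05, size_jitter_sd = 0.15,
                       detection_threshold = 50, seed = 1L) {
  stopifnot(
    eff_hpaii >= 0, eff_hpaii <= 1, eff_primary >= 0, eff_primary <= 1,
    eff_mspi >= 0, eff_mspi <= 1, gain > 0, noise_sigma >= 0,
    size_jitter_sd >= 0, detection_threshold >= 0
  )
  structure(list(eff_hpaii = eff_hpaii, eff_primary = eff_primary,
                 eff_mspi = eff_mspi, gain = gain, noise_sigma = noise_sigma,
                 size_jitter_sd = size_jitter_sd,
                 detection_threshold = detection_threshold,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Expected fragment abundances of an MSD library
#'
#' The methylation-dependent core of the chemistry: a fragment survives
#' library preparation only if the CpG of its terminal HpaII site was
#' methylated (methylation blocks the HpaII digest that otherwise removes the
#' adaptor required for amplification). The expected abundance of fragment
#' `f` with monitored-CpG methylation level `m` is
#' `eff_primary * eff_mspi * (m + (1 - m) * (1 - eff_hpaii))`,
#' which reduces to `m` when all digestions are complete.
#'
#' @param db A [build_fragment_db()] result.
#' @param profile Methylation profile: tibble with `chrom`, `cpg_pos`
#'   (1-based internal C of a CCGG) and `level` in `[0, 1]`.
#' @param params A [sim_params()] list.
#' @param default_level Level assumed (with a warning) for monitored CpGs
#'   missing from `profile`.
#' @return Tibble of class `msd_library`: the database rows plus `level` and
#'   `abundance`.
#' @export
simulate_library <- function(db, profile, params = sim_params(),
                             default_level = 0) {
  stop_if_missing_cols(profile, c("chrom", "cpg_pos", "level"), "profile")
  if (any(profile$level < 0 | profile$level > 1)) {
    abort("methylation levels must lie in [0, 1]")
  }
  lib <- as_tibble(db) |>
    left_join(profile |> select("chrom", "cpg_pos", "level"),
              by = c("chrom", "cpg_pos"))
  n_missing <- sum(is.na(lib$level))
  if (n_missing > 0) {
    warn(sprintf("%d monitored CpG(s) missing from profile; assuming level %g",
                 n_missing, default_level))
    lib$level[is.na(lib$level)] <- default_level
  }
  lib$abundance <- params$eff_primary * params$eff_mspi *
    (lib$level + (1 - lib$level) * (1 - params$eff_hpaii))
  class(lib) <- c("msd_library", class(tibble()))
  lib
}

#' Simulate one selective-PCR peak chart
#'
#' Amplifies the selective subset of the library and renders it as a
#' capillary electropherogram: fragments sharing one integer display length
#' co-migrate and their abundances sum into a single peak; each peak height
#' is `gain * abundance` perturbed by log-normal noise; the reported size is
#' the display length plus Gaussian sizing jitter; peaks below the detection
#' threshold are not called. Byte-identical output is guaranteed for
#' identical inputs and seed.
#'
#' @param library A [simulate_library()] result.
#' @param sel_primary,sel_secondary Selective dinucleotides of the primer
#'   pair.
#' @param params A [sim_params()] list.
#' @param sample Sample label stored in the chart.
#' @param seed Seed for this chart (defaults to `params$seed`).
#' @return Tibble of class `peak_chart` with columns `sample`, `sel_primary`,
#'   `sel_secondary`, `size`, `height`, ordered by size. The seed used is
#'   stored as attribute `seed`.
#' @export
simulate_peak_chart <- function(library, sel_primary, sel_secondary,
                                params = sim_params(), sample = "sample",
                                seed = NULL) {
  if (!is_nn(sel_primary) || !is_nn(sel_secondary)) {
    abort("selective bases must be length-2 strings over {A,C,G,T}")
  }
  seed <- as.integer(seed %||% params$seed)
  sub <- as_tibble(library) |>
    filter(.data$sel_primary == .env$sel_primary,
           .data$sel_secondary == .env$sel_secondary) |>
    group_by(.data$display_length) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    arrange(.data$display_length)
  chart <- withr::with_seed(seed, {
    height <- params$gain * sub$abundance *
      exp(rnorm(nrow(sub), 0, params$noise_sigma))
    size <- sub$display_length + rnorm(nrow(sub), 0, params$size_jitter_sd)
    tibble(sample = sample, sel_primary = sel_primary,
           sel_secondary = sel_secondary, size = size, height = height)
  })
  chart <- chart[chart$height >= params$detection_threshold, ]
  chart <- chart[order(chart$size), ]
  structure(chart, class = c("peak_chart", class(tibble())), seed = seed)
}

#' Simulate the fully methylated (SssI) reference chart
#'
#' Identical to [simulate_peak_chart()] with every monitored CpG forced to
#' level 1, emulating genomic DNA artificially methylated at all CpGs: the
#' theoretical fully methylated signal each sample peak is ratioed against.
#'
#' @inheritParams simulate_peak_chart
#' @param db A [build_fragment_db()] result.
#' @return A `peak_chart` tibble.
#' @export
simulate_reference_chart <- function(db, sel_primary, sel_secondary,
                                     params = sim_params(),
                                     sample = "SssI_reference", seed = NULL) {
  profile <- as_tibble(db) |>
    distinct(.data$chrom, .data$cpg_pos) |>
    mutate(level = 1)
  lib <- simulate_library(db, profile, params)
  simulate_peak_chart(lib, sel_primary, sel_secondary, params,
                      sample = sample, seed = seed)
}

#' Simulate an MSRE-PCR measurement of one CpG
#'
#' Models the paired-digest quantitative PCR: one genomic aliquot digested
#' with methylation-sensitive HpaII, the other with StuI (which cuts none of
#' the targets, so its copy number equals the template input). The HpaII
#' aliquot retains `m + (1 - m) * (1 - eff_hpaii)` of the template. Both
#' copy numbers are perturbed by log-normal qPCR noise of SD `noise_sigma`
#' unless `sampled = TRUE`, in which case surviving copies are drawn
#' binomially for finite-template realism.
#'
#' @param profile Methylation profile tibble (`chrom`, `cpg_pos`, `level`).
#' @param chrom,cpg_pos Coordinates of the queried CpG (must be in
#'   `profile`).
#' @param template_copies Template copy number per aliquot (> 0).
#' @param params A [sim_params()] list.
#' @param sampled Draw binomial copy counts instead of continuous
#'   expectations.
#' @param seed Seed (defaults to `params$seed`).
#' @return One-row tibble with `copies_hpaii`, `copies_stui`.
#' @export
simulate_msre <- function(profile, chrom, cpg_pos, template_copies = 1e4,
                          params = sim_params(), sampled = FALSE, seed = NULL) {
  stopifnot(template_copies > 0)
  m <- profile$level[profile$chrom == chrom & profile$cpg_pos == cpg_pos]
  if (length(m) != 1) {
    abort(sprintf("CpG %s:%s not present in profile", chrom, format(cpg_pos)))
  }
  surv <- m + (1 - m) * (1 - params$eff_hpaii)
  seed <- as.integer(seed %||% params$seed)
  withr::with_seed(seed, {
    if (sampled) {
      hp <- rbinom(1, size = round(template_copies), prob = surv)
      st <- round(template_copies)
    } else {
      hp <- template_copies * surv
      st <- template_copies
    }
    noise <- exp(rnorm(2, 0, params$noise_sigma))
    tibble(copies_hpaii = hp * noise[1], copies_stui = st * noise[2])
  })
}

#' Write / read peak charts as CSV
#'
#' The on-disk dialect is the one the quantification reader accepts: columns
#' `sample`, `sel_primary`, `sel_secondary`, `size`, `height`; several charts
#' may share one file.
#'
#' @param charts A `peak_chart` tibble or a row-bound collection of them.
#' @param path File path.
#' @return `path` invisibly; `read_peak_charts()` returns a tibble. The
#'   reader also accepts a GeneMapper-style export with columns `Sample`,
#'   `Dye`, `Size`, `Height` (optionally `Sel.Primary`/`Sel.Secondary`),
#'   filtered to `dye` (default the 6-FAM blue channel, "B").
#' @export
write_peak_charts <- function(charts, path) {
  readr::write_csv(as_tibble(charts), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_peak_charts
#' @param dye Dye channel kept when reading GeneMapper-style exports.
#' @export
read_peak_charts <- function(path, dye = "B") {
  raw <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  if (all(c("sample", "sel_primary", "sel_secondary", "size", "height") %in% names(raw))) {
    return(as_tibble(raw))
  }
  names(raw) <- tolower(gsub("[. ]", "_", names(raw)))
  if (all(c("sample", "dye", "size", "height") %in% names(raw))) {
    out <- raw |> filter(.data$dye == .env$dye)
    if (!"sel_primary" %in% names(out)) out$sel_primary <- NA_character_
    if (!"sel_secondary" %in% names(out)) out$sel_secondary <- NA_character_
    return(out |> select("sample", "sel_primary", "sel_secondary", "size", "height"))
  }
  abort("unrecognized peak chart file: need sample/sel_primary/sel_secondary/size/height or a GeneMapper-style Sample/Dye/Size/Height export")
}
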