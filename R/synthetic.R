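#' Specification of a synthetic genome
#'
#' Parameters of the synthetic-genome generator: random background sequence
#' of a chosen GC fraction with SbfI recognition sites and CCGG motifs
#' planted at random non-overlapping positions. The defaults emulate a small
#' mammal-like test genome: 2 chromosomes of 500 kb, ~150 SbfI sites per
#' chromosome and one CCGG every ~300 bp at GC fraction 0.42 (the mouse
#' genome average).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length, nt (>= 1000).
#' @param sbfi_per_chrom Target planted SbfI-site count per chromosome.
#' @param ccgg_per_kb Target planted CCGG density per kb.
#' @param gc GC fraction of the background sequence.
#' @param seed Integer seed.
#' @return List of class `synth_genome_spec`.
#' @export
synth_genome_spec <- function(n_chromosomes = 2, chrom_length = 5e5,
                              sbfi_per_chrom = 150, ccgg_per_kb = 10 / 3,
                              gc = 0.42, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 1000,
            sbfi_per_chrom >= 0, ccgg_per_kb >= 0, gc >= 0, gc <= 1)
  n_ccgg <- round(ccgg_per_kb * chrom_length / 1000)
  # planted motifs are kept non-overlapping with >= 8 nt spacing
  if ((sbfi_per_chrom + n_ccgg) * 16 > chrom_length) {
    abort("unsatisfiable genome spec: motif density too high for chromosome length")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 sbfi_per_chrom = as.integer(sbfi_per_chrom),
                 ccgg_per_kb = ccgg_per_kb, gc = gc, seed = as.integer(seed)),
            class = "synth_genome_spec")
}

#' Generate a synthetic genome with planted restriction sites
#'
#' Draws i.i.d. background sequence at the requested GC fraction, plants
#' SbfI (`CCTGCAGG`) and `CCGG` motifs at random non-overlapping positions,
#' then *re-scans its own output* so the emitted truth tables list the
#' realized sites — including accidental motifs created by the background —
#' not merely the planting plan. Deterministic given the spec seed.
#'
#' @param spec A [synth_genome_spec()].
#' @return List of class `synth_genome`: `genome` (named character vector),
#'   `sbfi_sites` and `ccgg_sites` (realized [find_sites()] tables), `spec`.
#' @export
generate_genome <- function(spec = synth_genome_spec()) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  sbfi_motif <- "CCTGCAGG"
  ccgg_motif <- "CCGG"
  probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
             G = spec$gc / 2, T = (1 - spec$gc) / 2)
  n_ccgg <- round(spec$ccgg_per_kb * spec$chrom_length / 1000)
  genome <- withr::with_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$n_chromosomes), function(i) {
      bases <- sample(names(probs), spec$chrom_length, replace = TRUE,
                      prob = probs)
      n_plant <- spec$sbfi_per_chrom + n_ccgg
      if (n_plant > 0) {
        n_cand <- min(n_plant * 4L, spec$chrom_length %/% 10L, spec$chrom_length - 8L)
        cand <- sort(sample.int(spec$chrom_length - 8L, n_cand))
        keep <- cand[c(TRUE, diff(cand) >= 16L)]
        if (length(keep) < n_plant) abort("could not place all motifs; lower the density")
        pos <- sample(keep, n_plant)
        motifs <- sample(c(rep(sbfi_motif, spec$sbfi_per_chrom),
                           rep(ccgg_motif, n_ccgg)))
        for (j in seq_along(pos)) {
          m <- strsplit(motifs[j], "")[[1]]
          bases[pos[j]:(pos[j] + length(m) - 1L)] <- m
        }
      }
      paste(bases, collapse = "")
    }, character(1))
    setNames(seqs, sprintf("chr%d", seq_len(spec$n_chromosomes)))
  })
  structure(
    list(genome = genome,
         sbfi_sites = find_sites(genome, "SbfI"),
         ccgg_sites = find_sites(genome, "HpaII"),
         spec = spec),
    class = "synth_genome"
  )
}

#' Specification of a synthetic methylation study
#'
#' The statistical structure mirrors a three-tissue mouse comparison with
#' three biological replicates each. Per CpG a baseline level is drawn from
#' `Beta(a, b)` (shared across tissues); the default `Beta(5, 2)` has mean
#' ~0.71, matching the high average CpG methylation of mammalian tissue
#' while spreading levels over the full signal-ratio range. Planted
#' tissue effects add `effect_size` (on the [0,1] level scale) to one tissue
#' at each selected CpG; replicates then receive additive Gaussian noise
#' `noise_sd` and are clamped to `[0, 1]`.
#'
#' @param tissues Tissue (group) labels.
#' @param replicates Biological replicates per tissue.
#' @param baseline_shape1,baseline_shape2 Beta parameters of the shared
#'   baseline level distribution.
#' @param n_planted Number of CpGs given a planted tissue effect.
#' @param effect_size Planted shift on the level scale (0.05 = 5 percentage
#'   points).
#' @param noise_sd Replicate noise SD on the level scale.
#' @param seed Integer seed.
#' @return List of class `synth_study_spec`.
#' @export
synth_study_spec <- function(tissues = c("liver", "kidney", "hippocampus"),
                             replicates = 3, baseline_shape1 = 5,
                             baseline_shape2 = 2, n_planted = 50,
                             effect_size = 0.05, noise_sd = 0.05, seed = 1L) {
  stopifnot(length(tissues) >= 2, replicates >= 1, baseline_shape1 > 0,
            baseline_shape2 > 0, n_planted >= 0, noise_sd >= 0)
  structure(list(tissues = tissues, replicates = as.integer(replicates),
                 baseline_shape1 = baseline_shape1,
                 baseline_shape2 = baseline_shape2,
                 n_planted = as.integer(n_planted),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_study_spec")
}

#' Generate a methylation study with known ground truth
#'
#' Draws per-CpG baselines, plants tissue effects, and realizes replicate
#' methylation profiles for every monitored CpG of a fragment database.
#' Deterministic given the spec seed.
#'
#' @param db A [build_fragment_db()] result (its distinct monitored CpGs
#'   define the methylome).
#' @param spec A [synth_study_spec()].
#' @return List of class `synth_study`: `samples` (tibble `sample`,
#'   `tissue`), `profiles` (long tibble `sample`, `tissue`, `chrom`,
#'   `cpg_pos`, `level`), `truth` (per CpG: baseline, planted flag, affected
#'   tissue, delta, and per-tissue pre-noise means), `spec`.
#' @export
generate_study <- function(db, spec = synth_study_spec()) {
  stopifnot(inherits(spec, "synth_study_spec"))
  cpgs <- as_tibble(db) |> distinct(.data$chrom, .data$cpg_pos) |>
    arrange(.data$chrom, .data$cpg_pos)
  n <- nrow(cpgs)
  if (n == 0) abort("empty fragment database")
  if (spec$n_planted > n) abort("more planted effects than CpGs in the database")
  tissues <- spec$tissues
  withr::with_seed(spec$seed, {
    baseline <- rbeta(n, spec$baseline_shape1, spec$baseline_shape2)
    planted_idx <- if (spec$n_planted > 0) sample.int(n, spec$n_planted) else integer(0)
    affected <- rep(NA_character_, n)
    affected[planted_idx] <- rep_len(tissues, length(planted_idx))
    delta <- ifelse(is.na(affected), 0, spec$effect_size)

    tissue_means <- vapply(tissues, function(tt) {
      clamp(baseline + ifelse(!is.na(affected) & affected == tt, spec$effect_size, 0), 0, 1)
    }, numeric(n))
    if (n == 1) tissue_means <- matrix(tissue_means, nrow = 1, dimnames = list(NULL, tissues))

    samples <- tidyr::expand_grid(tissue = tissues,
                                  rep = seq_len(spec$replicates)) |>
      mutate(sample = sprintf("%s_%d", .data$tissue, .data$rep)) |>
      select("sample", "tissue")
    profiles <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
      tt <- samples$tissue[i]
      lvl <- clamp(tissue_means[, tt] + rnorm(n, 0, spec$noise_sd), 0, 1)
      tibble(sample = samples$sample[i], tissue = tt,
             chrom = cpgs$chrom, cpg_pos = cpgs$cpg_pos, level = lvl)
    })
    truth <- cpgs |>
      mutate(baseline = baseline, planted = !is.na(affected),
             affected_tissue = affected, delta = delta) |>
      dplyr::bind_cols(dplyr::rename_with(as_tibble(tissue_means),
                                          ~ paste0("mean_", .x)))
    structure(list(samples = samples, profiles = profiles, truth = truth,
                   spec = spec),
              class = "synth_study")
  })
}

#' Write a complete self-contained study fixture
#'
#' Generates and writes everything an end-to-end MSD-AFLP analysis needs, in
#' the formats the other modules consume: genome FASTA, fragment-database
#' TSV, per-sample methylation profiles TSV, simulated peak charts CSV for
#' every study sample plus the fully methylated SssI reference (one chart per
#' selective-primer pair, default the `n_sel_pairs` most populated pairs,
#' emulating a 16-primer-set experiment), an 11-locus calibration TSV
#' pairing each locus's observed signal ratio with its simulated MSRE-PCR
#' percent (loci chosen non-co-migrating, spread across the SR range),
#' ground-truth tables, and a YAML manifest recording every seed.
#'
#' @param dir Output directory (created if needed).
#' @param genome_spec A [synth_genome_spec()].
#' @param study_spec A [synth_study_spec()].
#' @param params A [sim_params()]; per-chart seeds are derived from
#'   `params$seed`.
#' @param n_sel_pairs Number of selective-primer pairs to simulate.
#' @param n_calibration Number of calibration loci.
#' @param display_offset,size_range Forwarded to [build_fragment_db()].
#' @return Invisibly, a list with the in-memory objects (`genome`, `db`,
#'   `study`, `charts`, `calibration`, `sel_pairs`) and all file `paths`.
#' @export
make_fixture <- function(dir, genome_spec = synth_genome_spec(),
                         study_spec = synth_study_spec(),
                         params = sim_params(), n_sel_pairs = 16,
                         n_calibration = 11, display_offset = 0L,
                         size_range = c(50L, 500L)) {
  if (study_spec$replicates < 1) abort("need at least 1 replicate per tissue")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  sg <- generate_genome(genome_spec)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sg$genome), p("genome.fasta"))
  db <- build_fragment_db(sg$genome, display_offset = display_offset,
                          size_range = size_range, genome_label = "synthetic")
  if (nrow(db) == 0) abort("fixture genome yielded no fragments")
  write_fragment_db(db, p("fragment_db.tsv"))

  study <- generate_study(db, study_spec)
  readr::write_tsv(study$profiles, p("profiles.tsv"), progress = FALSE)
  readr::write_tsv(study$truth, p("truth.tsv"), progress = FALSE)
  readr::write_tsv(study$samples, p("samples.tsv"), progress = FALSE)

  sel_pairs <- as_tibble(db) |>
    dplyr::count(.data$sel_primary, .data$sel_secondary, sort = TRUE) |>
    head(n_sel_pairs) |>
    select("sel_primary", "sel_secondary")

  charts <- list()
  chart_seeds <- list()
  k <- 0L
  for (i in seq_len(nrow(sel_pairs))) {
    sp <- sel_pairs$sel_primary[i]; ss <- sel_pairs$sel_secondary[i]
    for (j in seq_len(nrow(study$samples))) {
      k <- k + 1L
      seed_k <- derive_seed(params$seed, k)
      prof <- study$profiles |> filter(.data$sample == study$samples$sample[j])
      lib <- simulate_library(db, prof, params)
      charts[[k]] <- simulate_peak_chart(lib, sp, ss, params,
                                         sample = study$samples$sample[j],
                                         seed = seed_k)
      chart_seeds[[k]] <- list(sample = study$samples$sample[j],
                               sel_primary = sp, sel_secondary = ss,
                               seed = seed_k)
    }
    k <- k + 1L
    seed_k <- derive_seed(params$seed, k)
    charts[[k]] <- simulate_reference_chart(db, sp, ss, params, seed = seed_k)
    chart_seeds[[k]] <- list(sample = "SssI_reference", sel_primary = sp,
                             sel_secondary = ss, seed = seed_k)
  }
  all_charts <- bind_rows(charts)
  write_peak_charts(all_charts, p("charts.csv"))

  calibration <- fixture_calibration(db, study, all_charts, sel_pairs, params,
                                     n_calibration)
  write_calibration(calibration, p("calibration.tsv"))

  manifest <- list(
    seeds = list(genome = genome_spec$seed, study = study_spec$seed,
                 charts_base = params$seed),
    genome_spec = unclass(genome_spec), study_spec = unclass(study_spec),
    sim_params = unclass(params),
    n_sel_pairs = nrow(sel_pairs), n_calibration = n_calibration,
    files = list(genome = "genome.fasta", db = "fragment_db.tsv",
                 profiles = "profiles.tsv", truth = "truth.tsv",
                 samples = "samples.tsv", charts = "charts.csv",
                 calibration = "calibration.tsv")
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))

  invisible(list(genome = sg, db = db, study = study, charts = all_charts,
                 calibration = calibration, sel_pairs = sel_pairs,
                 paths = list(dir = dir, genome = p("genome.fasta"),
                              db = p("fragment_db.tsv"),
                              profiles = p("profiles.tsv"),
                              truth = p("truth.tsv"), samples = p("samples.tsv"),
                              charts = p("charts.csv"),
                              calibration = p("calibration.tsv"),
                              manifest = p("manifest.yaml"))))
}

# Calibration loci: non-co-migrating fragments of the simulated pairs,
# spread across the observed SR range; SR from the first sample's chart,
# MSRE percent simulated on the same sample's profile.
fixture_calibration <- function(db, study, all_charts, sel_pairs, params,
                                n_calibration) {
  cal_sample <- study$samples$sample[1]
  frag <- as_tibble(db) |>
    inner_join(sel_pairs, by = c("sel_primary", "sel_secondary")) |>
    group_by(.data$sel_primary, .data$sel_secondary, .data$display_length) |>
    filter(n() == 1L) |>
    ungroup()
  prof <- study$profiles |> filter(.data$sample == cal_sample)
  frag <- frag |> left_join(prof |> select("chrom", "cpg_pos", "level"),
                            by = c("chrom", "cpg_pos"))
  frag <- frag[order(frag$level), ]
  if (nrow(frag) < n_calibration) {
    abort("not enough non-co-migrating fragments for the calibration")
  }
  pick <- frag[unique(round(seq(1, nrow(frag), length.out = n_calibration))), ]

  out <- purrr::map_dfr(seq_len(nrow(pick)), function(i) {
    f <- pick[i, ]
    samp <- all_charts |>
      filter(.data$sample == cal_sample,
             .data$sel_primary == f$sel_primary,
             .data$sel_secondary == f$sel_secondary,
             abs(.data$size - f$display_length) <= 0.5)
    ref <- all_charts |>
      filter(.data$sample == "SssI_reference",
             .data$sel_primary == f$sel_primary,
             .data$sel_secondary == f$sel_secondary,
             abs(.data$size - f$display_length) <= 0.5)
    sr <- if (nrow(ref) == 1 && ref$height > 0) {
      (if (nrow(samp) == 1) samp$height else 0) / ref$height
    } else NA_real_
    msre <- simulate_msre(prof, f$chrom, f$cpg_pos, template_copies = 1e4,
                          params = params,
                          seed = derive_seed(params$seed, 900 + i))
    tibble(locus = sprintf("%s:%d", f$chrom, f$cpg_pos),
           chrom = f$chrom, cpg_pos = f$cpg_pos,
           display_length = f$display_length,
           sel_primary = f$sel_primary, sel_secondary = f$sel_secondary,
           true_level = f$level, sr = sr,
           msre_percent = msre_percent(msre))
  })
  out[!is.na(out$sr), ]
}

#' Ground-truth methylation data of a study in analysis format
#'
#' Converts the realized per-replicate levels of a [generate_study()] result
#' to the long percent-methylation format consumed by [anova_bh()] and
#' friends (`cpg`, `sample`, `group`, `percent`), e.g. to run the
#' statistical pipeline directly on simulated truth.
#'
#' @param study A [generate_study()] result.
#' @return Long tibble with `cpg` (`chrom:cpg_pos`), `sample`, `group`,
#'   `percent`.
#' @export
study_meth_data <- function(study) {
  stopifnot(inherits(study, "synth_study"))
  study$profiles |>
    mutate(cpg = sprintf("%s:%d", .data$chrom, .data$cpg_pos),
           percent = 100 * .data$level) |>
    select("cpg", "sample", group = "tissue", "percent")
}
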