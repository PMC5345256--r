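#' Build the virtual MSD-AFLP fragment database
#'
#' Re-creates, in silico, the set of fragments an MSD-AFLP library can display:
#' for every primary-enzyme site (SbfI by default), the genomic insert running
#' from the primary cut to the *nearest* secondary-enzyme site (HpaII/MspI,
#' CCGG) in each direction. A direction yields no fragment when no secondary
#' site lies within the same primary digestion fragment, when the display
#' length falls outside `size_range`, or when the selective bases cannot be
#' read (insert too short, or `N` in a selective window).
#'
#' Coordinates are 0-based half-open. For a `"+"` fragment (CCGG 3' of the
#' SbfI site) the insert is `[site_start + top_cut, ccgg_start + 1)`; for a
#' `"-"` fragment it is `[ccgg_start + 1, site_start + len - top_cut)`, i.e.
#' each insert keeps the SbfI sticky-end remnant on its primary side and runs
#' to the HpaII top-strand cut on its secondary side. The monitored CpG is the
#' internal C of the nearest CCGG, reported 1-based (`ccgg_start + 2`).
#'
#' Selective dinucleotides are the two genomic bases each selective primer
#' reads immediately beyond its enzyme remnant, reported 5'->3' on the strand
#' that primer extends: for `"+"` fragments `sel_primary` is read on the
#' forward strand just past the SbfI recognition sequence and `sel_secondary`
#' is the reverse complement of the two forward-strand bases 5' of the CCGG;
#' for `"-"` fragments the two conventions swap strands.
#'
#' @param genome Named character vector or `DNAStringSet` (see [as_genome()]).
#' @param primary,secondary Enzyme names or specs (see [msd_enzymes()]).
#' @param display_offset Constant (adaptor/primer) length added to the insert
#'   length to give the electrophoresed display length, in nt. Default 0:
#'   display lengths equal genomic insert lengths; set it to the summed
#'   adaptor contribution for bit-exact emulation of a sizing run.
#' @param size_range Two-element numeric, inclusive display-length window kept
#'   in the database. Default `c(50, 500)`, the range sized by a 500-nt
#'   capillary size standard.
#' @param genome_label Free-text label stored with the database.
#' @return A tibble of class `fragment_db`, sorted by chromosome, insert
#'   start and orientation, with columns `chrom`, `orientation`,
#'   `insert_start`, `insert_end`, `insert_length`, `display_length`,
#'   `sel_primary`, `sel_secondary`, `cpg_pos` (1-based). Attributes carry the
#'   enzymes, `display_offset`, `size_range`, `genome_label` and the
#'   unfiltered candidate count (`n_candidates`) together with per-rule drop
#'   counts.
#' @examples
#' db <- build_fragment_db(c(c1 = "AACCTGCAGGTACGTACCGGTT"), size_range = c(1, 500))
#' db
#' @export
build_fragment_db <- function(genome, primary = "SbfI", secondary = "HpaII",
                              display_offset = 0L, size_range = c(50L, 500L),
                              genome_label = "genome") {
  genome <- as_genome(genome)
  pz <- enzyme_spec(primary)
  sz <- enzyme_spec(secondary)
  stopifnot(length(size_range) == 2, size_range[1] >= 1, size_range[1] <= size_range[2])
  display_offset <- as.integer(display_offset)

  p_sites <- find_sites(genome, pz)
  s_sites <- find_sites(genome, sz)

  lp <- nchar(pz$recognition); tp <- as.integer(pz$top_cut_offset)
  ls <- nchar(sz$recognition); ts <- as.integer(sz$top_cut_offset)
  cpg_off <- as.integer(sz$blocking_cpg_offset %||% 1L)
  if (is.na(cpg_off)) cpg_off <- 1L

  per_chrom <- purrr::map(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    P <- p_sites$site_start[p_sites$chrom == chrom]
    S <- s_sites$site_start[s_sites$chrom == chrom]
    if (length(P) == 0 || length(S) == 0) return(NULL)
    k <- length(P)

    # "+": nearest CCGG fully inside [cut, next primary cut)
    lo <- P + tp
    hi <- c(if (k > 1) P[-1] + tp else integer(0), L)
    i_plus <- findInterval(lo - 0.5, S) + 1L
    ok_plus <- i_plus <= length(S) & S[pmin(i_plus, length(S))] + ls <= hi
    plus <- tibble(
      chrom = chrom, orientation = "+",
      p = P[ok_plus], s = S[i_plus[ok_plus]],
      insert_start = P[ok_plus] + tp,
      insert_end = S[i_plus[ok_plus]] + ts
    )

    # "-": nearest CCGG fully inside (prev primary boundary, bottom-strand cut]
    hi2 <- P + (lp - tp)
    lo2 <- c(0L, if (k > 1) P[-k] + (lp - tp) else integer(0))
    i_minus <- findInterval(hi2 - ls, S)
    ok_minus <- i_minus >= 1L & S[pmax(i_minus, 1L)] >= lo2
    minus <- tibble(
      chrom = chrom, orientation = "-",
      p = P[ok_minus], s = S[i_minus[ok_minus]],
      insert_start = S[i_minus[ok_minus]] + ts,
      insert_end = P[ok_minus] + (lp - tp)
    )

    frags <- bind_rows(plus, minus)
    if (nrow(frags) == 0) return(NULL)
    frags$insert_length <- frags$insert_end - frags$insert_start
    frags$cpg_pos <- frags$s + cpg_off + 1L  # 1-based internal C of CCGG
    sel <- selective_windows(frags, seq, lp, tp, ls)
    frags$sel_primary <- sel$sel_primary
    frags$sel_secondary <- sel$sel_secondary
    frags
  })

  cand <- bind_rows(per_chrom)
  n_candidates <- nrow(cand)
  if (n_candidates == 0) {
    cand <- tibble(chrom = character(), orientation = character(),
                   insert_start = integer(), insert_end = integer(),
                   insert_length = integer(), display_length = integer(),
                   sel_primary = character(), sel_secondary = character(),
                   cpg_pos = integer())
    return(new_fragment_db(cand, pz, sz, display_offset, size_range,
                           genome_label, 0L, 0L, 0L))
  }

  sel_ok <- is_nn(cand$sel_primary) & is_nn(cand$sel_secondary)
  n_dropped_sel <- sum(!sel_ok)
  if (n_dropped_sel > 0) {
    inform(sprintf(
      "dropped %d fragment(s) with unreadable selective bases (insert < 4 nt or N)",
      n_dropped_sel))
  }
  cand <- cand[sel_ok, ]
  cand$display_length <- cand$insert_length + display_offset
  in_range <- cand$display_length >= size_range[1] & cand$display_length <= size_range[2]
  n_dropped_size <- sum(!in_range)
  cand <- cand[in_range, ]

  out <- cand |>
    select("chrom", "orientation", "insert_start", "insert_end",
           "insert_length", "display_length", "sel_primary", "sel_secondary",
           "cpg_pos") |>
    arrange(.data$chrom, .data$insert_start, .data$orientation)
  new_fragment_db(out, pz, sz, display_offset, size_range, genome_label,
                  n_candidates, n_dropped_sel, n_dropped_size)
}

# Selective windows for a candidate table on one chromosome; NA when the
# window leaves the insert or the chromosome.
selective_windows <- function(frags, seq, lp, tp, ls) {
  L <- nchar(seq)
  plus <- frags$orientation == "+"
  sp <- ss <- rep(NA_character_, nrow(frags))
  p <- frags$p; s <- frags$s
  a <- frags$insert_start; b <- frags$insert_end

  # "+": SbfI primer reads forward just past the recognition sequence;
  #      MspI primer reads the bottom strand 5' of the CCGG.
  i <- which(plus & (p + lp + 2L) <= b)
  sp[i] <- substr(rep(seq, length(i)), p[i] + lp + 1L, p[i] + lp + 2L)
  i <- which(plus & (s - 2L) >= a)
  ss[i] <- revcomp(substr(rep(seq, length(i)), s[i] - 1L, s[i]))

  # "-": mirrored conventions.
  i <- which(!plus & (p - 2L) >= a)
  sp[i] <- revcomp(substr(rep(seq, length(i)), p[i] - 1L, p[i]))
  i <- which(!plus & (s + ls + 2L) <= b)
  ss[i] <- substr(rep(seq, length(i)), s[i] + ls + 1L, s[i] + ls + 2L)

  sp[!is_nn(sp)] <- NA_character_
  ss[!is_nn(ss)] <- NA_character_
  list(sel_primary = sp, sel_secondary = ss)
}

new_fragment_db <- function(tbl, pz, sz, display_offset, size_range,
                            genome_label, n_candidates, n_dropped_sel,
                            n_dropped_size) {
  structure(
    tbl,
    class = c("fragment_db", class(tibble())),
    primary = pz$name, secondary = sz$name,
    display_offset = as.integer(display_offset),
    size_range = as.numeric(size_range),
    genome_label = genome_label,
    n_candidates = as.integer(n_candidates),
    n_dropped_sel = as.integer(n_dropped_sel),
    n_dropped_size = as.integer(n_dropped_size)
  )
}

#' Read the selective dinucleotides of fragments
#'
#' Recomputes `sel_primary` and `sel_secondary` for a table of fragments
#' against the genome, using the strand conventions documented in
#' [build_fragment_db()]. Fragments whose inserts are too short to carry both
#' selective windows (insert length < 4 nt) are returned with `NA` selective
#' bases and a warning.
#'
#' @param fragments Tibble with `chrom`, `orientation`, `insert_start`,
#'   `insert_end` and `cpg_pos` columns (e.g. rows of a [build_fragment_db()]
#'   result).
#' @param genome The genome the fragments were built from.
#' @param primary,secondary Enzyme names or specs.
#' @return `fragments` with `sel_primary`/`sel_secondary` (re)filled.
#' @export
selective_bases <- function(fragments, genome, primary = "SbfI",
                            secondary = "HpaII") {
  genome <- as_genome(genome)
  pz <- enzyme_spec(primary); sz <- enzyme_spec(secondary)
  lp <- nchar(pz$recognition); tp <- as.integer(pz$top_cut_offset)
  ls <- nchar(sz$recognition)
  fragments <- as_tibble(fragments)
  stop_if_missing_cols(fragments,
                       c("chrom", "orientation", "insert_start", "insert_end", "cpg_pos"),
                       "fragment table")
  # recover recognition starts from the insert span
  s <- ifelse(fragments$orientation == "+",
              fragments$insert_end - as.integer(sz$top_cut_offset),
              fragments$insert_start - as.integer(sz$top_cut_offset))
  p <- ifelse(fragments$orientation == "+",
              fragments$insert_start - tp,
              fragments$insert_end - (lp - tp))
  idx_split <- split(seq_len(nrow(fragments)), fragments$chrom)
  out <- purrr::map(idx_split, function(i) {
    fr <- fragments[i, ]
    fr$p <- p[i]; fr$s <- s[i]
    sel <- selective_windows(fr, genome[[fr$chrom[1]]], lp, tp, ls)
    fr$sel_primary <- sel$sel_primary
    fr$sel_secondary <- sel$sel_secondary
    fr$p <- NULL; fr$s <- NULL
    fr
  })
  res <- bind_rows(out)[order(unlist(idx_split)), ]
  n_bad <- sum(!is_nn(res$sel_primary) | !is_nn(res$sel_secondary))
  if (n_bad > 0) {
    warn(sprintf("%d fragment(s) too short for selective bases; excluded (NA)", n_bad))
  }
  res
}

#' Size-uniqueness report of a fragment database
#'
#' Within each selective-primer subset (one `sel_primary` x `sel_secondary`
#' pair amplifies one chart), a fragment is *single-peak* when no other
#' fragment of the same subset shares its integer display length; co-migrating
#' fragments merge into one ambiguous peak. The overall single-peak fraction
#' is the key resolution statistic of the method.
#'
#' @param db A [build_fragment_db()] result.
#' @return List of class `uniqueness_report`: `by_subset` (tibble keyed by the
#'   selective pair with `n_fragments`, `n_single_peak`), `total_fragments`,
#'   `n_single_peak`, `fraction_single`, plus the unfiltered candidate count
#'   carried over from the database.
#' @export
uniqueness_report <- function(db) {
  if (nrow(db) == 0) abort("empty fragment database")
  by_subset <- as_tibble(db) |>
    group_by(.data$sel_primary, .data$sel_secondary, .data$display_length) |>
    summarise(n = n(), .groups = "drop_last") |>
    summarise(
      n_fragments = sum(.data$n),
      n_single_peak = sum(.data$n[.data$n == 1L]),
      .groups = "drop"
    )
  structure(
    list(
      by_subset = by_subset,
      total_fragments = sum(by_subset$n_fragments),
      n_single_peak = sum(by_subset$n_single_peak),
      fraction_single = sum(by_subset$n_single_peak) / sum(by_subset$n_fragments),
      n_candidates_unfiltered = attr(db, "n_candidates")
    ),
    class = "uniqueness_report"
  )
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf(
    "MSD-AFLP size-uniqueness report\n  fragments in database: %d (of %d unfiltered candidates)\n  single-peak fragments: %d (%.1f%%)\n  selective subsets occupied: %d\n",
    x$total_fragments, x$n_candidates_unfiltered %||% NA_integer_,
    x$n_single_peak, 100 * x$fraction_single, nrow(x$by_subset)))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy uniqueness_report
#' @export
tidy.uniqueness_report <- function(x, ...) x$by_subset

#' Retrieve candidate loci for an observed peak
#'
#' The locus-prediction query: all database fragments in the matching
#' selective subset whose display length is within `tolerance` nt of the
#' observed peak size, nearest first (ties broken by genomic position). The
#' result may be empty, or contain several candidates when distinct loci
#' co-migrate.
#'
#' @param db A [build_fragment_db()] result.
#' @param sel_primary,sel_secondary Length-2 selective dinucleotides (ACGT).
#' @param observed_size Observed peak size in nt.
#' @param tolerance Size tolerance in nt (>= 0).
#' @return Subset of `db` rows with an extra `size_delta` column.
#' @export
query_loci <- function(db, sel_primary, sel_secondary, observed_size,
                       tolerance = 0) {
  if (!is_nn(sel_primary) || !is_nn(sel_secondary)) {
    abort("selective bases must be length-2 strings over {A,C,G,T}")
  }
  stopifnot(tolerance >= 0)
  out <- as_tibble(db) |>
    filter(.data$sel_primary == .env$sel_primary,
           .data$sel_secondary == .env$sel_secondary) |>
    mutate(size_delta = abs(.data$display_length - .env$observed_size)) |>
    filter(.data$size_delta <= .env$tolerance) |>
    arrange(.data$size_delta, .data$chrom, .data$insert_start)
  out
}

#' Fraction of monitored CpGs inside annotated genes
#'
#' @param db A [build_fragment_db()] result.
#' @param gene_intervals Tibble of 0-based half-open intervals (`chrom`,
#'   `start`, `end`), e.g. from [read_intervals()].
#' @return One-row tibble with `n_inside`, `n_total`, `fraction`.
#' @export
intragenic_fraction <- function(db, gene_intervals) {
  if (nrow(db) == 0) abort("empty fragment database")
  stop_if_missing_cols(gene_intervals, c("chrom", "start", "end"), "gene intervals")
  pos <- as_tibble(db) |>
    mutate(.row = dplyr::row_number(), pos0 = .data$cpg_pos - 1L) |>
    select(".row", "chrom", "pos0")
  iv <- as_tibble(gene_intervals) |>
    mutate(last = .data$end - 1L) |>
    select("chrom", "start", "last")
  hits <- inner_join(pos, iv,
                     by = join_by("chrom", between("pos0", "start", "last")))
  n_inside <- dplyr::n_distinct(hits$.row)
  tibble(n_inside = n_inside, n_total = nrow(db),
         fraction = n_inside / nrow(db))
}

#' Serialize / read a fragment database as TSV
#'
#' The file starts with `#key=value` metadata lines (genome label, enzymes,
#' display offset, size range, candidate counts) followed by a TSV of the
#' records, so query results are reproducible from the file alone.
#'
#' @param db A [build_fragment_db()] result.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_fragment_db()` returns the `fragment_db`.
#' @export
write_fragment_db <- function(db, path) {
  meta <- c(
    genome_label = attr(db, "genome_label"),
    primary = attr(db, "primary"),
    secondary = attr(db, "secondary"),
    display_offset = attr(db, "display_offset"),
    size_min = attr(db, "size_range")[1],
    size_max = attr(db, "size_range")[2],
    n_candidates = attr(db, "n_candidates"),
    n_dropped_sel = attr(db, "n_dropped_sel"),
    n_dropped_size = attr(db, "n_dropped_size")
  )
  readr::write_lines(sprintf("#%s=%s", names(meta), as.character(meta)), path)
  readr::write_tsv(as_tibble(db), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_fragment_db
#' @export
read_fragment_db <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- stringr::str_match(meta_lines, "^#([^=]+)=(.*)$")
  meta <- setNames(kv[, 3], kv[, 2])
  tbl <- readr::read_tsv(I(lines[!grepl("^#", lines)]), progress = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           orientation = readr::col_character(),
                           sel_primary = readr::col_character(),
                           sel_secondary = readr::col_character(),
                           .default = readr::col_integer()
                         ))
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  new_fragment_db(tbl,
                  pz = list(name = meta[["primary"]]),
                  sz = list(name = meta[["secondary"]]),
                  display_offset = as.integer(meta[["display_offset"]]),
                  size_range = as.numeric(c(meta[["size_min"]], meta[["size_max"]])),
                  genome_label = meta[["genome_label"]],
                  n_candidates = as.integer(meta[["n_candidates"]]),
                  n_dropped_sel = as.integer(meta[["n_dropped_sel"]]),
                  n_dropped_size = as.integer(meta[["n_dropped_size"]]))
}
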