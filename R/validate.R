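#' Brute-force reference implementation of the virtual digest
#'
#' An independent, deliberately naive re-derivation of
#' [build_fragment_db()], used to validate the vectorized builder: it scans
#' each chromosome character by character for the primary and secondary
#' recognition sequences, then walks outward from every primary cut to the
#' nearest secondary site in each direction, applying the same exclusion
#' rules (secondary site fully inside the primary digestion fragment,
#' selective windows inside the insert, no `N`, display length within range)
#' by direct string inspection. It shares no code path with the builder
#' beyond the enzyme table.
#'
#' @inheritParams build_fragment_db
#' @return A tibble with the same columns as [build_fragment_db()].
#' @export
build_fragment_db_reference <- function(genome, primary = "SbfI",
                                        secondary = "HpaII",
                                        display_offset = 0L,
                                        size_range = c(50L, 500L)) {
  genome <- as_genome(genome)
  pz <- enzyme_spec(primary); sz <- enzyme_spec(secondary)
  lp <- nchar(pz$recognition); tp <- pz$top_cut_offset
  ls <- nchar(sz$recognition); ts <- sz$top_cut_offset
  scan <- function(seq, rec) {
    L <- nchar(seq); r <- nchar(rec)
    if (L < r) return(integer(0))
    windows <- substring(seq, 1:(L - r + 1), r:L)
    which(windows == rec) - 1L  # 0-based
  }
  rows <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    P <- scan(seq, pz$recognition)
    S <- scan(seq, sz$recognition)
    for (p in P) {
      nxt <- P[P > p]
      prv <- P[P < p]
      # forward: nearest CCGG fully inside this primary digestion fragment
      hi <- if (length(nxt)) min(nxt) + tp else L
      s_fw <- S[S >= p + tp & S + ls <= hi]
      if (length(s_fw)) {
        s <- min(s_fw)
        a <- p + tp; b <- s + ts
        sel_p <- if (p + lp + 2 <= b) substr(seq, p + lp + 1, p + lp + 2) else NA
        sel_s <- if (s - 2 >= a) revcomp(substr(seq, s - 1, s)) else NA
        rows[[length(rows) + 1]] <- list(
          chrom = chrom, orientation = "+", insert_start = a, insert_end = b,
          sel_primary = sel_p, sel_secondary = sel_s, cpg_pos = s + 2L)
      }
      # backward
      lo <- if (length(prv)) max(prv) + (lp - tp) else 0L
      hi2 <- p + (lp - tp)
      s_bw <- S[S >= lo & S + ls <= hi2]
      if (length(s_bw)) {
        s <- max(s_bw)
        a <- s + ts; b <- hi2
        sel_p <- if (p - 2 >= a) revcomp(substr(seq, p - 1, p)) else NA
        sel_s <- if (s + ls + 2 <= b) substr(seq, s + ls + 1, s + ls + 2) else NA
        rows[[length(rows) + 1]] <- list(
          chrom = chrom, orientation = "-", insert_start = a, insert_end = b,
          sel_primary = sel_p, sel_secondary = sel_s, cpg_pos = s + 2L)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(chrom = character(), orientation = character(),
                  insert_start = integer(), insert_end = integer(),
                  insert_length = integer(), display_length = integer(),
                  sel_primary = character(), sel_secondary = character(),
                  cpg_pos = integer()))
  }
  out <- bind_rows(lapply(rows, as_tibble))
  out$insert_start <- as.integer(out$insert_start)
  out$insert_end <- as.integer(out$insert_end)
  out$cpg_pos <- as.integer(out$cpg_pos)
  out$insert_length <- out$insert_end - out$insert_start
  out$display_length <- out$insert_length + as.integer(display_offset)
  ok <- !is.na(out$sel_primary) & !is.na(out$sel_secondary) &
    grepl("^[ACGT]{2}$", out$sel_primary) & grepl("^[ACGT]{2}$", out$sel_secondary) &
    out$display_length >= size_range[1] & out$display_length <= size_range[2]
  out <- out[ok, c("chrom", "orientation", "insert_start", "insert_end",
                   "insert_length", "display_length", "sel_primary",
                   "sel_secondary", "cpg_pos")]
  out[order(out$chrom, out$insert_start, out$orientation), ]
}
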