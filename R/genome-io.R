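#' Read a genome from FASTA
#'
#' Reads a (optionally gzipped) FASTA file into a named character vector, one
#' element per chromosome, uppercased. Soft-masked (lowercase) bases are
#' treated as ordinary sequence. Record order is preserved; record names are
#' truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences over `{A,C,G,T,N}`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA: %s", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  as_genome(seqs)
}

#' Coerce to the internal genome representation
#'
#' Accepts a named character vector or a [Biostrings::DNAStringSet] and
#' returns a validated named character vector of uppercase sequences.
#'
#' @param x Genome-like object.
#' @return Named character vector.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) abort("genome must be a named character vector or DNAStringSet")
  if (is.null(names(x)) || any(is.na(names(x))) || any(names(x) == "")) {
    abort("all chromosomes must be named")
  }
  if (anyDuplicated(names(x))) {
    abort(sprintf("duplicate chromosome name(s): %s",
                  paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
  }
  x <- toupper(x)
  if (any(nchar(x) == 0)) abort("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("non-nucleotide characters in chromosome(s): %s",
                  paste(names(x)[bad], collapse = ", ")))
  }
  x
}

#' Locate restriction enzyme recognition sites
#'
#' Scans the forward strand of every chromosome for the enzyme's recognition
#' sequence. Only palindromic recognition sequences are supported (every
#' enzyme shipped with the package is palindromic), so forward-strand hits
#' describe both strands. IUPAC ambiguity codes in the recognition sequence
#' are honored; windows containing `N` in the genome are never sites.
#' Overlapping matches are all reported.
#'
#' @param genome Named character vector (see [as_genome()]).
#' @param enzyme Enzyme name or spec (see [enzyme_spec()]).
#' @return A tibble with columns `chrom`, `site_start` (0-based start of the
#'   recognition window) and `cut_coord` (0-based index of the first base 3'
#'   of the top-strand cut, i.e. `site_start + top_cut_offset`), sorted by
#'   `chrom` then `site_start`.
#' @examples
#' find_sites(c(c1 = "CCGGCCGG"), "HpaII")
#' @export
find_sites <- function(genome, enzyme) {
  genome <- as_genome(genome)
  ez <- enzyme_spec(enzyme)
  if (!is_palindromic(ez$recognition)) {
    abort(sprintf("enzyme %s: non-palindromic recognition '%s' is not supported",
                  ez$name, ez$recognition))
  }
  pat <- Biostrings::DNAString(ez$recognition)
  fixed <- c(pattern = FALSE, subject = TRUE)  # IUPAC in pattern, literal genome
  hits <- purrr::map2(names(genome), unname(genome), function(chrom, seq) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq), fixed = fixed)
    tibble(chrom = chrom, site_start = Biostrings::start(m) - 1L)
  })
  out <- bind_rows(hits)
  out$cut_coord <- out$site_start + as.integer(ez$top_cut_offset)
  out
}

#' Count exact motif occurrences in a genome
#'
#' Counts forward-strand occurrences of `motif` summed over chromosomes.
#' Overlapping occurrences are counted (e.g. `"CG"` in `"CGCGCG"` counts 3).
#'
#' @param genome Named character vector (see [as_genome()]).
#' @param motif Motif over `{A,C,G,T}`.
#' @return Integer count.
#' @examples
#' count_motif(c(c1 = "CCGGCCGG"), "CCGG")
#' @export
count_motif <- function(genome, motif) {
  genome <- as_genome(genome)
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) == 0) {
    abort("motif must be a non-empty string")
  }
  if (grepl("[^ACGT]", motif)) abort("motif must be over {A,C,G,T}")
  pat <- Biostrings::DNAString(motif)
  sum(vapply(genome, function(seq) {
    Biostrings::countPattern(pat, Biostrings::DNAString(seq), fixed = TRUE)
  }, integer(1)))
}

#' Read genomic intervals from BED or GFF3
#'
#' Intervals are normalized to the package-wide 0-based half-open convention.
#' BED input is read as-is; GFF3 input (1-based closed) is converted, keeping
#' only features of type `feature_type`. Malformed lines are reported with
#' their line number.
#'
#' @param path Path to the interval file.
#' @param format `"bed"` or `"gff3"`.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3"), feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (format == "bed") {
    parse_bed_lines(fields, idx)
  } else {
    parse_gff3_lines(fields, idx, feature_type)
  }
}

parse_bed_lines <- function(fields, line_no) {
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED line %d: fewer than 3 columns", line_no[which(nf < 3)[1]]))
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) abort(sprintf("BED line %d: non-integer coordinates", line_no[which(bad)[1]]))
  rev <- end < start | start < 0
  if (any(rev)) {
    abort(sprintf("BED line %d: end < start (or negative start)", line_no[which(rev)[1]]))
  }
  score <- suppressWarnings(as.double(get(5)))
  tibble(
    chrom = get(1), start = start, end = end,
    name = dplyr::coalesce(get(4), "."),
    score = dplyr::coalesce(score, 0),
    strand = dplyr::coalesce(get(6), ".")
  )
}

parse_gff3_lines <- function(fields, line_no, feature_type) {
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(sprintf("GFF3 line %d: fewer than 9 columns", line_no[which(nf < 9)[1]]))
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  start <- suppressWarnings(as.integer(get(4)))
  end <- suppressWarnings(as.integer(get(5)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) abort(sprintf("GFF3 line %d: non-integer coordinates", line_no[which(bad)[1]]))
  rev <- end < start | start < 1
  if (any(rev)) abort(sprintf("GFF3 line %d: end < start (1-based closed expected)", line_no[which(rev)[1]]))
  keep <- get(3) == feature_type
  id <- stringr::str_match(get(9), "(?:^|;)\\s*(?:ID|Name)=([^;]+)")[, 2]
  score <- suppressWarnings(as.double(get(6)))
  tibble(
    chrom = get(1), start = start - 1L, end = end,
    name = dplyr::coalesce(id, "."),
    score = dplyr::coalesce(score, 0),
    strand = get(7)
  )[keep, ]
}

#' Write records as BED6
#'
#' Writes one BED6 line per record. The score column carries percent
#' methylation rescaled to 0-1000 when a `percent` column is present
#' (BED-style 0-1000 score), else 0; the strand column carries the fragment
#' orientation when present.
#'
#' @param records A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open); optional `name`, `percent`, `strand`/`orientation`. A
#'   [build_fragment_db()] result works directly (`insert_start`/`insert_end`
#'   are used as the span and the monitored CpG as the name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  df <- as_tibble(records)
  if (!"start" %in% names(df) && "insert_start" %in% names(df)) {
    df$start <- df$insert_start
    df$end <- df$insert_end
  }
  stop_if_missing_cols(df, c("chrom", "start", "end"), "BED input")
  if (any(df$end < df$start)) abort("BED records must have end >= start")
  name <- if ("name" %in% names(df)) df$name else if ("cpg_pos" %in% names(df)) {
    sprintf("%s:%d", df$chrom, df$cpg_pos)
  } else rep(".", nrow(df))
  score <- if ("percent" %in% names(df)) {
    as.integer(round(clamp(df$percent, 0, 100) * 10))
  } else rep(0L, nrow(df))
  strand <- if ("strand" %in% names(df)) df$strand else
    if ("orientation" %in% names(df)) df$orientation else rep(".", nrow(df))
  out <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                 df$chrom, as.integer(df$start), as.integer(df$end),
                 name, score, strand)
  readr::write_lines(out, path)
  invisible(path)
}
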