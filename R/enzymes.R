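#' Restriction enzymes shipped with the package
#'
#' Returns the bundled enzyme table: recognition sequence, top-strand cut
#' offset (bases from the start of the recognition sequence to the first base
#' 3' of the cut), and, for methylation-sensitive enzymes, the offset of the C
#' of the CpG whose methylation blocks cleavage. All shipped enzymes have
#' palindromic recognition sequences, so forward-strand scanning finds every
#' site. The table lives in `extdata/enzymes.tsv`; users can point
#' `enzyme_table` at an extended copy to add enzymes.
#'
#' The set covers the MSD-AFLP chemistry (SbfI primary digest, HpaII/MspI
#' isoschizomers at CCGG, StuI as the MSRE-PCR control cut) plus the
#' alternative primary enzymes NcoI, AseI, BspHI, PacI and SwaI.
#'
#' @param enzyme_table Optional path to a TSV with columns `name`,
#'   `recognition`, `top_cut_offset`, `blocking_cpg_offset`,
#'   `methylation_sensitive`.
#' @return A tibble with one row per enzyme.
#' @examples
#' msd_enzymes()
#' @export
msd_enzymes <- function(enzyme_table = NULL) {
  path <- enzyme_table %||%
    system.file("extdata", "enzymes.tsv", package = "msdaflp", mustWork = TRUE)
  tab <- readr::read_tsv(
    path, na = "NA", progress = FALSE,
    col_types = readr::cols(
      name = readr::col_character(),
      recognition = readr::col_character(),
      top_cut_offset = readr::col_integer(),
      blocking_cpg_offset = readr::col_integer(),
      methylation_sensitive = readr::col_logical()
    )
  )
  validate_enzyme_table(tab)
  tab
}

validate_enzyme_table <- function(tab) {
  stop_if_missing_cols(tab, c("name", "recognition", "top_cut_offset",
                              "blocking_cpg_offset", "methylation_sensitive"),
                       "enzyme table")
  if (anyDuplicated(tab$name)) abort("enzyme table has duplicate names")
  bad_cut <- tab$top_cut_offset < 0 | tab$top_cut_offset > nchar(tab$recognition)
  if (any(bad_cut)) {
    abort(sprintf("top_cut_offset outside recognition for: %s",
                  paste(tab$name[bad_cut], collapse = ", ")))
  }
  has_block <- !is.na(tab$blocking_cpg_offset)
  if (any(has_block)) {
    off <- tab$blocking_cpg_offset[has_block]
    rec <- tab$recognition[has_block]
    ok <- substr(rec, off + 1, off + 2) == "CG"
    if (!all(ok)) abort("blocking_cpg_offset must index a C followed by G")
  }
  invisible(tab)
}

#' Look up one enzyme as a list
#'
#' @param enzyme Enzyme name (e.g. `"SbfI"`), or a one-row data frame / list
#'   with the same fields as [msd_enzymes()], passed through unchanged.
#' @param enzyme_table Optional path forwarded to [msd_enzymes()].
#' @return A list with fields `name`, `recognition`, `top_cut_offset`,
#'   `blocking_cpg_offset`, `methylation_sensitive`.
#' @export
enzyme_spec <- function(enzyme, enzyme_table = NULL) {
  if (is.list(enzyme) && !is.data.frame(enzyme)) {
    stopifnot(all(c("name", "recognition", "top_cut_offset") %in% names(enzyme)))
    return(enzyme)
  }
  if (is.data.frame(enzyme)) {
    stopifnot(nrow(enzyme) == 1)
    return(as.list(enzyme))
  }
  tab <- msd_enzymes(enzyme_table)
  hit <- tab[tab$name == enzyme, ]
  if (nrow(hit) != 1) abort(sprintf("unknown enzyme '%s'", enzyme))
  as.list(hit)
}

is_palindromic <- function(recognition) {
  identical(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition))),
    recognition
  )
}
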