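clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Reverse-complement a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that works on plain
#' character vectors (IUPAC codes allowed).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "TTA"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_nn <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[ACGT]{2}$", x)
}

# deterministic small sub-seed derivation; stays well below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(k) %% 1000L)
}

stop_if_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}
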