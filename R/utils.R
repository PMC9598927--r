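#' Normalize miRNA identifiers across database dialects
#'
#' Arrays and target databases disagree on capitalisation and on the
#' species prefix; this maps all dialects onto a common key so edges and
#' expression rows join correctly. The identifier is lower-cased and a
#' leading "hsa-" is stripped; the arm suffix (-5p/-3p) carries real
#' biological meaning and is preserved.
#'
#' @param x Character vector of miRNA identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_mirna_id(c("hsa-miR-182-5p", "MIR-182-5P"))
#' @export
normalize_mirna_id <- function(x) {
  x <- tolower(as.character(x))
  sub("^hsa-", "", x)
}

# shared validators ---------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  x
}

#' @noRd
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2L)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(expr[[1]])
  m
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
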