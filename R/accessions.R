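#' Normalize UniProt-style protein accessions
#'
#' Canonicalizes raw accession strings so protein sets taken from different
#' studies become comparable: surrounding whitespace is stripped, the string
#' is upper-cased, and (by default) an isoform suffix of the form `-<digits>`
#' is removed so isoforms of one protein merge into a single identifier.
#' The function is deterministic and idempotent.
#'
#' @param x Character vector of raw accessions.
#' @param strip_isoform Drop a trailing `-<digits>` isoform suffix
#'   (default `TRUE`).
#' @return Character vector of normalized accessions, same length as `x`.
#' @examples
#' normalize_accession(c("A0A096MJ53", "p04639-2", "  Q9Z2L0 "))
#' @export
normalize_accession <- function(x, strip_isoform = TRUE) {
  if (!is.character(x)) {
    abort_validation("`x` must be a character vector of accessions.")
  }
  out <- toupper(trimws(x))
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    abort_validation(sprintf(
      "Malformed protein identifier: empty or whitespace-only accession at position(s) %s.",
      paste(which(bad), collapse = ", ")
    ))
  }
  if (strip_isoform) {
    out <- sub("-[0-9]+$", "", out)
  }
  out
}

#' @noRd
condition_types <- function() {
  c("normoxia", "hypoxia", "OGD", "stroke", "other")
}

# Validation errors carry a class so the CLI can map them to exit code 2
# (internal-consistency errors map to 3).
abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "evmeta_validation_error", ...)
}

abort_internal <- function(msg, ...) {
  rlang::abort(msg, class = "evmeta_internal_error", ...)
}
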