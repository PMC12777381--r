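#' Validate SNOMED CT identifiers
#'
#' A SCTID is a string of 6 to 18 decimal digits without a leading zero.
#' Validation is syntactic by default; `strict = TRUE` additionally verifies
#' the trailing Verhoeff check digit that real SNOMED CT identifiers carry.
#' Synthetic identifiers used in generated fixtures are valid syntactically
#' but generally do not carry a meaningful check digit, so strict mode is
#' off by default.
#'
#' @param id character vector of candidate identifiers.
#' @param strict logical; also verify the Verhoeff check digit.
#' @return logical vector, one element per input.
#' @examples
#' is_sctid(c("64572001", "012345", "12", "not-an-id"))
#' @export
is_sctid <- function(id, strict = FALSE) {
  ok <- is.character(id) & grepl("^[1-9][0-9]{5,17}$", id)
  if (strict) {
    ok <- ok & vapply(id, function(x) ok_verhoeff(x), logical(1), USE.NAMES = FALSE)
  }
  ok
}

# Verhoeff dihedral-group tables
.verhoeff_d <- matrix(c(
  0,1,2,3,4,5,6,7,8,9,
  1,2,3,4,0,6,7,8,9,5,
  2,3,4,0,1,7,8,9,5,6,
  3,4,0,1,2,8,9,5,6,7,
  4,0,1,2,3,9,5,6,7,8,
  5,9,8,7,6,0,4,3,2,1,
  6,5,9,8,7,1,0,4,3,2,
  7,6,5,9,8,2,1,0,4,3,
  8,7,6,5,9,3,2,1,0,4,
  9,8,7,6,5,4,3,2,1,0), nrow = 10, byrow = TRUE)

.verhoeff_p <- matrix(c(
  0,1,2,3,4,5,6,7,8,9,
  1,5,7,6,2,8,3,0,9,4,
  5,8,0,3,7,9,6,1,4,2,
  8,9,1,6,0,4,3,5,2,7,
  9,4,5,3,1,2,6,8,7,0,
  4,2,8,6,5,7,3,9,0,1,
  2,7,9,3,8,0,6,4,1,5,
  7,0,4,6,9,1,3,2,5,8), nrow = 8, byrow = TRUE)

ok_verhoeff <- function(x) {
  if (!grepl("^[0-9]+$", x)) return(FALSE)
  digits <- rev(as.integer(strsplit(x, "")[[1]]))
  c_val <- 0L
  for (i in seq_along(digits)) {
    c_val <- .verhoeff_d[c_val + 1L, .verhoeff_p[((i - 1L) %% 8L) + 1L, digits[i] + 1L] + 1L]
  }
  c_val == 0L
}

#' @keywords internal
assert_sctid <- function(id, what = "concept id") {
  bad <- !is_sctid(id)
  if (any(bad)) {
    stop(errorCondition(
      sprintf("invalid %s: %s", what, paste(id[bad], collapse = ", ")),
      class = c("eclkit_sctid_error", "eclkit_error")
    ))
  }
  invisible(id)
}

# sort SCTIDs in numeric order without losing precision on 18-digit ids:
# no leading zeros, so shorter strings are numerically smaller and equal-length
# strings compare lexicographically.
sct_sort <- function(ids) {
  ids <- unique(as.character(ids))
  ids[order(nchar(ids), ids, method = "radix")]
}
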