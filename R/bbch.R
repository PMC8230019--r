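#' BBCH event catalogue for olive
#'
#' The 19 phenological events of the olive BBCH centesimal scale that the
#' package recognises, from swelling foliar buds (01) to at least 50% of
#' fruits fallen (99).
#'
#' @return A data frame with columns `code` (integer, 0-99) and
#'   `description`.
#' @examples
#' bbch_catalogue()
#' @export
bbch_catalogue <- function() {
  data.frame(
    code = c(1L, 3L, 7L, 11L, 50L, 51L, 55L, 61L, 65L, 68L, 69L,
             71L, 75L, 80L, 81L, 85L, 89L, 92L, 99L),
    description = c(
      "Foliar buds start to swell and open",
      "Foliar buds lengthen and separate from base",
      "External small leaves open, not completely separated",
      "First leaves completely separated",
      "Inflorescence buds leaf axils completely closed",
      "Inflorescence buds start to swell",
      "Flower cluster totally expanded",
      "Beginning of flowering",
      "Full flowering, at least 50% of flowers open",
      "Majority of petals fallen or faded",
      "End of flowering, non-fertilized ovaries fallen",
      "Fruits at 10% of final size",
      "Fruits at 50% of final size",
      "Fruit becoming light green or yellowish",
      "Beginning of fruit coloring",
      "Increasing specific fruit coloring",
      "Harvest maturity",
      "Overripe with fruits that start to fall",
      "At least 50% of fruits fallen"),
    stringsAsFactors = FALSE
  )
}

#' Validate BBCH codes against the olive catalogue
#'
#' @param code Integer vector of BBCH codes.
#' @return The codes, invisibly, after validation.
#' @keywords internal
validate_bbch <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L) || any(code > 99L)) {
    stop("BBCH codes must be integers in [0, 99]", call. = FALSE)
  }
  bad <- setdiff(code, bbch_catalogue()$code)
  if (length(bad) > 0L) {
    stop("unknown BBCH code(s) for olive: ",
         paste(sort(bad), collapse = ", "),
         " (see bbch_catalogue())", call. = FALSE)
  }
  invisible(code)
}
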