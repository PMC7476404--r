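#' Well addresses on a 96-well plate
#'
#' Wells are written `"A1"`..`"H12"` (row letter A-H, column 1-12, no zero
#' padding). All plate iteration in this package is column-major
#' (A1, B1, ..., H1, A2, ...), matching common robot deck conventions.
#'
#' @param x character vector of well labels.
#' @return `wellAddress()` returns the normalised labels (upper case, no
#'   padding); it throws an error on anything that is not a valid well.
#' @examples
#' wellAddress(c("a1", "H12"))
#' wellIndex("A2")   # 9: column-major, 8 rows per column
#' indexToWell(48)   # "H6"
#' @export
wellAddress <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-H])0*([1-9][0-9]?)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid well address(es): ", paste(unique(x[bad]), collapse = ", "))
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col > 12L)) {
    stop("well column out of range 1-12: ", paste(unique(x[col > 12L]), collapse = ", "))
  }
  paste0(row, col)
}

#' @rdname wellAddress
#' @export
wellRow <- function(x) substr(wellAddress(x), 1L, 1L)

#' @rdname wellAddress
#' @export
wellColumn <- function(x) as.integer(substring(wellAddress(x), 2L))

#' @rdname wellAddress
#' @export
wellIndex <- function(x) {
  x <- wellAddress(x)
  (wellColumn(x) - 1L) * 8L + match(wellRow(x), LETTERS[1:8])
}

#' @rdname wellAddress
#' @param i column-major well index, 1-96.
#' @export
indexToWell <- function(i) {
  i <- as.integer(i)
  if (any(is.na(i) | i < 1L | i > 96L)) stop("well index out of range 1-96")
  paste0(LETTERS[(i - 1L) %% 8L + 1L], (i - 1L) %/% 8L + 1L)
}

is_well <- function(x) {
  !inherits(try(wellAddress(x), silent = TRUE), "try-error")
}
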