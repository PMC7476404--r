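## Minimal GenBank flat-file writer/reader for predicted constructs and
## stored parts. Covers the subset this package emits: LOCUS with topology,
## DEFINITION, misc_feature entries with /label, and ORIGIN. Coordinates in
## the file are 1-based inclusive, per the format; in-memory features are
## 0-based half-open.

formatGenbankOrigin <- function(seq) {
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = 60L)
  lines <- vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(tens), collapse = " "))
  }, "")
  lines
}

#' Write one record in GenBank flat-file format
#'
#' @param name locus name.
#' @param seq plus-strand sequence.
#' @param file output path.
#' @param circular logical topology flag.
#' @param features data.frame with `start`, `end` (0-based half-open),
#'   `type`, `label`; may be NULL.
#' @param definition one-line description.
#' @return the file path, invisibly.
#' @export
writeGenbankRecord <- function(name, seq, file, circular = TRUE,
                               features = NULL, definition = "") {
  topo <- if (circular) "circular" else "linear"
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-1980",
            name, nchar(seq), topo),
    sprintf("DEFINITION  %s", if (nzchar(definition)) definition else name),
    sprintf("ACCESSION   %s", name),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq))
  )
  if (!is.null(features) && nrow(features) > 0L) {
    for (i in seq_len(nrow(features))) {
      loc <- sprintf("%d..%d", features$start[i] + 1L, features$end[i])
      out <- c(out,
               sprintf("     misc_feature    %s", loc),
               sprintf("                     /label=\"%s\"", features$label[i]),
               sprintf("                     /note=\"%s\"", features$type[i]))
    }
  }
  out <- c(out, "ORIGIN", formatGenbankOrigin(seq), "//")
  writeLines(out, file)
  invisible(file)
}

#' Read records from a GenBank flat file
#'
#' Parses the subset written by [writeGenbankRecord()]: locus name, length,
#' topology, misc_feature spans with labels, and the ORIGIN sequence.
#'
#' @param file path to a GenBank flat file (may hold several records).
#' @return list of records, each a list with `name`, `seq` (upper case),
#'   `circular`, and a `features` data.frame (0-based half-open).
#' @export
readGenbank <- function(file) {
  lines <- readLines(file)
  recStarts <- grep("^LOCUS", lines)
  if (!length(recStarts)) stop("no LOCUS line found in ", file)
  recEnds <- c(recStarts[-1L] - 1L, length(lines))
  records <- lapply(seq_along(recStarts), function(k) {
    block <- lines[recStarts[k]:recEnds[k]]
    locus <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    name <- locus[2L]
    circular <- any(grepl("circular", block[1L], fixed = TRUE))
    ori <- grep("^ORIGIN", block)
    if (!length(ori)) stop("record '", name, "' has no ORIGIN section")
    seqLines <- block[(ori + 1L):length(block)]
    seqLines <- seqLines[!grepl("^//", seqLines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
    if (grepl("[^ACGT]", seq))
      stop("alphabet error: record '", name, "' contains non-ACGT characters")
    featIdx <- grep("^\\s{5}misc_feature\\s", block)
    features <- data.frame(start = integer(), end = integer(),
                           type = character(), label = character(),
                           stringsAsFactors = FALSE)
    for (i in featIdx) {
      loc <- regmatches(block[i], regexec("(\\d+)\\.\\.(\\d+)", block[i]))[[1L]]
      lab <- ""; typ <- "misc"
      j <- i + 1L
      while (j <= length(block) && grepl("^\\s{21}/", block[j])) {
        q <- regmatches(block[j], regexec('/(label|note)="([^"]*)"', block[j]))[[1L]]
        if (length(q) == 3L) {
          if (q[2L] == "label") lab <- q[3L] else typ <- q[3L]
        }
        j <- j + 1L
      }
      features <- rbind(features, data.frame(
        start = as.integer(loc[2L]) - 1L, end = as.integer(loc[3L]),
        type = typ, label = lab, stringsAsFactors = FALSE))
    }
    list(name = name, seq = seq, circular = circular, features = features)
  })
  names(records) <- vapply(records, `[[`, "", "name")
  records
}
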