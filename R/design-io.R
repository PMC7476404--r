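#' Parse a construct-design CSV
#'
#' Dialect: comma-separated UTF-8 with a header row. Each data row is
#' `construct name, destination well, linker, part, linker, part, ...` —
#' the element list alternates linker and part names starting with a
#' linker and is interpreted circularly. Trailing empty cells are ignored
#' and names are whitespace-trimmed.
#'
#' @param content CSV text (single string or character vector of lines), or
#'   a file path via `file`.
#' @param file path to a CSV file (used when `content` is missing).
#' @return list of [ConstructDesign-class], in file order. A header-only
#'   file yields an empty list.
#' @examples
#' txt <- c("name,well,e1,e2,e3,e4",
#'          "C1,A1,LMS,backbone,LMP,insert")
#' parseConstructCsv(txt)
#' @export
parseConstructCsv <- function(content, file = NULL) {
  lines <- csvLines(content, file)
  if (length(lines) <= 1L) return(list())
  rows <- lapply(strsplit(lines[-1L], ",", fixed = TRUE),
                 function(x) trimws(x))
  designs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    cells <- rows[[i]]
    # drop trailing empties only
    while (length(cells) && !nzchar(cells[length(cells)]))
      cells <- cells[-length(cells)]
    if (length(cells) == 0L) next
    if (length(cells) < 2L)
      stop("row ", i, ": expected construct name and destination well")
    elements <- cells[-(1:2)]
    if (any(!nzchar(elements)))
      stop("row ", i, " ('", cells[1L], "'): empty element cell")
    if (length(elements) %% 2L != 0L || length(elements) < 4L)
      stop("row ", i, " ('", cells[1L],
           "'): malformed alternation - element count must be even and >= 4 ",
           "(linker, part, linker, part, ...)")
    designs[[i]] <- constructDesign(cells[1L], cells[2L], elements)
  }
  designs <- Filter(Negate(is.null), designs)
  wells <- vapply(designs, destinationWell, "")
  if (anyDuplicated(wells))
    stop("conflict: duplicate destination well(s): ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  designs
}

#' Write construct designs to CSV (inverse of [parseConstructCsv()])
#'
#' @param designs list of [ConstructDesign-class].
#' @param file output path; when NULL the CSV text is returned.
#' @return the CSV lines, invisibly when written to a file.
#' @export
writeConstructCsv <- function(designs, file = NULL) {
  nel <- if (length(designs)) {
    max(vapply(designs, function(d) length(designElements(d)), 1L))
  } else 0L
  header <- paste(c("name", "well", if (nel > 0L) paste0("element", seq_len(nel))),
                  collapse = ",")
  rows <- vapply(designs, function(d) {
    el <- designElements(d)
    paste(c(designName(d), destinationWell(d), el,
            rep("", nel - length(el))), collapse = ",")
  }, "")
  out <- c(header, rows)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Parse a source-plate CSV
#'
#' Dialect: header row then `name,well` rows. For linker plates every row
#' is a half-linker named `<linker>-P` (prefix half) or `<linker>-S`
#' (suffix half); both halves of a linker must be present for it to be
#' usable by a design.
#'
#' @inheritParams parseConstructCsv
#' @param kind `"part"` or `"linker"`.
#' @param plateId plate label (defaults to the file name or the kind).
#' @return a [PlateMap-class].
#' @export
parsePlateCsv <- function(content, kind = c("part", "linker"), file = NULL,
                          plateId = NULL) {
  kind <- match.arg(kind)
  if (is.null(plateId))
    plateId <- if (!is.null(file)) basename(file) else paste0(kind, "_plate")
  lines <- csvLines(content, file)
  if (length(lines) <= 1L)
    return(plateMap(plateId, stats::setNames(character(), character()), kind))
  tab <- utils::read.csv(text = lines, header = TRUE,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2L) stop("plate CSV needs name and well columns")
  nm <- trimws(tab[[1L]])
  wl <- trimws(tab[[2L]])
  keep <- nzchar(nm) | nzchar(wl)
  nm <- nm[keep]; wl <- wl[keep]
  if (kind == "linker" && any(!grepl("-[PS]$", nm)))
    stop("linker plate rows must be named '<linker>-P' or '<linker>-S'; bad: ",
         paste(nm[!grepl("-[PS]$", nm)], collapse = ", "))
  plateMap(plateId, stats::setNames(wl, nm), kind)
}

#' Write a plate map to CSV
#' @param plate a [PlateMap-class].
#' @param file output path; when NULL the CSV text is returned.
#' @export
writePlateCsv <- function(plate, file = NULL) {
  ent <- plateEntries(plate)
  out <- c("name,well", paste(names(ent), ent, sep = ","))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Half-linker inventory of a linker plate
#'
#' @param plate a linker-kind [PlateMap-class].
#' @return data.frame with `linker`, `half` (`"prefix"`/`"suffix"`), `well`.
#' @export
linkerHalves <- function(plate) {
  ent <- plateEntries(plate)
  nm <- names(ent)
  data.frame(
    linker = sub("-[PS]$", "", nm),
    half = ifelse(grepl("-P$", nm), "prefix", "suffix"),
    well = unname(ent),
    stringsAsFactors = FALSE)
}

issue <- function(severity, code, subject, message) {
  data.frame(severity = severity, code = code, subject = subject,
             message = message, stringsAsFactors = FALSE)
}

#' Validate construct designs against the source plates
#'
#' A pure check: identical inputs always give the identical issue table in
#' the same order. Errors: duplicate construct names or destination wells,
#' unknown reagents, alternation violations (a part name in a linker slot
#' or vice versa), linkers with a missing half. Warnings: plate reagents no
#' design uses.
#'
#' @param designs list of [ConstructDesign-class].
#' @param parts part-plate [PlateMap-class].
#' @param linkers linker-plate [PlateMap-class].
#' @return data.frame of issues with columns `severity` (`"error"` /
#'   `"warning"`), `code`, `subject`, `message`; zero rows means valid.
#' @export
validateDesigns <- function(designs, parts, linkers) {
  issues <- list()
  push <- function(x) issues[[length(issues) + 1L]] <<- x

  halves <- linkerHalves(linkers)
  partNames <- names(plateEntries(parts))
  fullLinkers <- intersect(halves$linker[halves$half == "prefix"],
                           halves$linker[halves$half == "suffix"])
  allLinkers <- unique(halves$linker)

  nms <- vapply(designs, designName, "")
  if (anyDuplicated(nms))
    push(issue("error", "duplicate_name",
               paste(unique(nms[duplicated(nms)]), collapse = ","),
               "duplicate construct name(s)"))
  wl <- vapply(designs, destinationWell, "")
  if (anyDuplicated(wl))
    push(issue("error", "duplicate_well",
               paste(unique(wl[duplicated(wl)]), collapse = ","),
               "duplicate destination well(s)"))

  for (d in designs) {
    el <- designElements(d)
    for (j in seq_along(el)) {
      nm <- el[j]
      linkerSlot <- j %% 2L == 1L
      if (linkerSlot) {
        if (nm %in% fullLinkers) next
        if (nm %in% allLinkers) {
          push(issue("error", "missing_half", designName(d),
                     sprintf("linker '%s' has only one half on plate '%s'",
                             nm, plateId(linkers))))
        } else if (nm %in% partNames) {
          push(issue("error", "alternation", designName(d),
                     sprintf("part '%s' found in a linker position (element %d)",
                             nm, j)))
        } else {
          push(issue("error", "unknown_reagent", designName(d),
                     sprintf("linker '%s' not found on plate '%s'",
                             nm, plateId(linkers))))
        }
      } else {
        if (nm %in% partNames) next
        if (nm %in% c(allLinkers, names(plateEntries(linkers)))) {
          push(issue("error", "alternation", designName(d),
                     sprintf("linker '%s' found in a part position (element %d)",
                             nm, j)))
        } else {
          push(issue("error", "unknown_reagent", designName(d),
                     sprintf("part '%s' not found on plate '%s'",
                             nm, plateId(parts))))
        }
      }
    }
  }

  usedParts <- unique(unlist(lapply(designs, designParts)))
  usedLinkers <- unique(unlist(lapply(designs, designLinkers)))
  for (nm in setdiff(partNames, usedParts))
    push(issue("warning", "unused_reagent", nm,
               sprintf("part '%s' on plate '%s' is unused", nm, plateId(parts))))
  for (nm in setdiff(allLinkers, usedLinkers))
    push(issue("warning", "unused_reagent", nm,
               sprintf("linker '%s' on plate '%s' is unused", nm, plateId(linkers))))

  if (!length(issues))
    return(issue("error", "x", "x", "x")[0, ])
  do.call(rbind, issues)
}

#' Write an issue table as JSON lines
#' @param issues data.frame from [validateDesigns()].
#' @param file output path.
#' @export
writeIssuesJson <- function(issues, file) {
  con <- base::file(file, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(issues)))
    writeLines(jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE), con)
  invisible(file)
}

#' Read part/construct sequences from FASTA or GenBank files
#'
#' FASTA records are read as linear; GenBank records keep their circular/
#' linear topology flag. Sequences are upper-cased and must be pure
#' A/C/G/T.
#'
#' @param paths character vector of file paths (`.fa`/`.fasta`/`.fna` or
#'   `.gb`/`.gbk`/`.genbank`).
#' @return named list of [PartSequence-class], keyed by record name.
#' @export
readSequences <- function(paths) {
  out <- list()
  for (p in paths) {
    recs <- if (grepl("\\.(gb|gbk|genbank)$", p, ignore.case = TRUE)) {
      lapply(readGenbank(p), function(r)
        partSequence(r$name, r$seq,
                     topology = if (r$circular) "circular" else "linear"))
    } else {
      ss <- Biostrings::readDNAStringSet(p)
      seqs <- toupper(as.character(ss))
      bad <- grepl("[^ACGT]", seqs)
      if (any(bad))
        stop("alphabet error: non-ACGT characters in record(s): ",
             paste(names(ss)[bad], collapse = ", "))
      mapply(function(nm, s) partSequence(sub("\\s.*", "", nm), s, "linear"),
             names(ss), seqs, SIMPLIFY = FALSE)
    }
    names(recs) <- vapply(recs, function(r) r@name, "")
    dup <- intersect(names(recs), names(out))
    if (length(dup))
      stop("conflict: duplicate record name(s): ", paste(dup, collapse = ", "))
    out <- c(out, recs)
  }
  out
}

csvLines <- function(content, file = NULL) {
  if (missing(content) || is.null(content)) {
    if (is.null(file)) stop("supply CSV content or a file path")
    content <- readLines(file, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(content, collapse = "\n"), "\r?\n"))
  lines[nzchar(trimws(lines))]
}
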