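#' Type IIS restriction model
#'
#' Default is BsaI: recognition `GGTCTC`, a 1-nt spacer, then a 4-nt 5'
#' overhang; both orientations are scanned. Cutting the plus-strand site
#' `GGTCTC N |NNNN` releases the downstream fragment with the 4-nt region
#' as a 5' extension of the top strand; the mirror applies to minus-strand
#' sites (`GAGACC` on the plus strand). A site carrying a methyl mark
#' anywhere inside the recognition sequence is never cut.
#'
#' @param recognition recognition sequence (plus strand).
#' @param spacer bases between recognition and overhang.
#' @param overhangLength overhang length (nt).
#' @return a restriction model (list with class `RestrictionModel`).
#' @examples
#' restrictionModel()  # BsaI
#' @export
restrictionModel <- function(recognition = "GGTCTC", spacer = 1L,
                             overhangLength = 4L) {
  recognition <- toupper(recognition)
  if (grepl("[^ACGT]", recognition)) stop("recognition must be A/C/G/T")
  structure(list(recognition = recognition, spacer = as.integer(spacer),
                 overhangLength = as.integer(overhangLength)),
            class = "RestrictionModel")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Locate recognition sites on both strands of a (possibly circular)
## sequence. Returns a data.frame: pos (1-based start of the recognition
## hit on the plus strand, within 1..n), strand ("+"/"-"), protected.
findRecognitionSites <- function(seq, model = restrictionModel(),
                                 methyl = integer(), circular = FALSE) {
  n <- nchar(seq)
  rec <- model$recognition
  k <- nchar(rec)
  scan <- if (circular && n >= k) paste0(seq, substr(seq, 1L, k - 1L)) else seq
  hits <- function(pattern) {
    m <- gregexpr(pattern, scan, fixed = TRUE)[[1L]]
    p <- m[m > 0L]
    p[p <= n]  # wrap starts only counted once
  }
  plusPos <- hits(rec)
  minusPos <- hits(revcomp(rec))
  siteSpan <- function(p) ((p - 1L):(p + k - 2L)) %% n + 1L
  prot <- function(p) length(methyl) > 0L && any(siteSpan(p) %in% methyl)
  df <- rbind(
    if (length(plusPos)) data.frame(pos = plusPos, strand = "+",
                                    stringsAsFactors = FALSE),
    if (length(minusPos)) data.frame(pos = minusPos, strand = "-",
                                     stringsAsFactors = FALSE))
  if (is.null(df))
    return(data.frame(pos = integer(), strand = character(),
                      protected = logical(), stringsAsFactors = FALSE))
  df$protected <- vapply(df$pos, prot, TRUE)
  df[order(df$pos, df$strand), , drop = FALSE]
}

#' Digest a stored part: release the core with its scar overhangs
#'
#' A valid stored part carries exactly one unprotected plus-strand site
#' (in the Prefix) and one unprotected minus-strand site (in the Suffix)
#' flanking the part core. Digestion returns the core as a
#' [DnaFragment-class] whose first and last 4 nt are the Prefix-end and
#' Suffix-end scar overhangs.
#'
#' @param part a [PartSequence-class] (or [PredictedConstruct-class], whose
#'   regenerated Prefix/Suffix release the assembled payload).
#' @param model a [restrictionModel()].
#' @return a [DnaFragment-class] with 4-nt overhangs at both ends.
#' @export
setGeneric("digestPart", function(part, model = restrictionModel())
  standardGeneric("digestPart"))

#' @rdname digestPart
#' @export
setMethod("digestPart", "PartSequence", function(part, model = restrictionModel()) {
  digestCore(part@seq, circular = part@topology == "circular",
             methyl = part@methyl, model = model, what = part@name)
})

#' @rdname digestPart
#' @export
setMethod("digestPart", "PredictedConstruct",
function(part, model = restrictionModel()) {
  digestCore(part@seq, circular = TRUE, methyl = integer(), model = model,
             what = part@name)
})

digestCore <- function(seq, circular, methyl, model, what = "sequence") {
  sites <- findRecognitionSites(seq, model, methyl, circular)
  act <- sites[!sites$protected, , drop = FALSE]
  if (nrow(act) < 2L)
    stop("missing-site error: '", what, "' has ", nrow(act),
         " unprotected recognition site(s); need one per strand")
  if (nrow(act) > 2L)
    stop("internal-site error: '", what, "' has ", nrow(act),
         " unprotected recognition sites at position(s) ",
         paste(act$pos, act$strand, collapse = ", "),
         "; expected exactly 2")
  plus <- act[act$strand == "+", , drop = FALSE]
  minus <- act[act$strand == "-", , drop = FALSE]
  if (nrow(plus) != 1L || nrow(minus) != 1L)
    stop("missing-site error: '", what,
         "' needs one unprotected site per strand (found ", nrow(plus),
         " plus, ", nrow(minus), " minus)")
  n <- nchar(seq)
  k <- nchar(model$recognition)
  ov <- model$overhangLength
  sp <- model$spacer
  p <- plus$pos   # GGTCTC starts here; core top strand starts at p+k+sp
  q <- minus$pos  # GAGACC starts here; core bottom-cut boundary at q-sp-1
  from <- p + k + sp          # first base of the released core (1-based)
  to <- q - sp - 1L           # last base of the released core
  if (circular) {
    idx <- ((from - 1L):(from + (to - from) %% n + n * ((to - from) %% n == 0 & to != from) - 1L))
    # simpler: walk forward from `from` to `to` with wrap
    len <- (to - from) %% n + 1L
    idx <- ((from - 1L) + 0:(len - 1L)) %% n + 1L
    core <- paste(strsplit(seq, "")[[1L]][idx], collapse = "")
  } else {
    if (from > to)
      stop("missing-site error: '", what,
           "' sites do not face each other across a core")
    core <- substr(seq, from, to)
  }
  if (nchar(core) < 2L * ov)
    stop("digest of '", what, "' yields a core shorter than its overhangs")
  dnaFragment(core, lOvh = ov, rOvh = ov, meta = list(name = what))
}

#' Ligate a part core to its two half-linkers, forming a clip
#'
#' The prefix (P-) half joins the core's left (Prefix-end) scar overhang,
#' the suffix (S-) half its right (Suffix-end) scar. The product is the
#' linear clip molecule: 21-base tail, prefix-half core, part core,
#' suffix-half core, 21-base tail.
#'
#' @param core a [DnaFragment-class] from [digestPart()].
#' @param linkerPrefix the [LinkerSequence-class] supplying the prefix
#'   half (the linker upstream of the part in the design).
#' @param linkerSuffix the [LinkerSequence-class] supplying the suffix
#'   half (the linker downstream of the part).
#' @return a [DnaFragment-class] with 21-base tails at both ends.
#' @export
ligateClip <- function(core, linkerPrefix, linkerSuffix) {
  ph <- dnaFragment(linkerPrefix@prefixSeq, lOvh = linkerPrefix@tailLength,
                    rOvh = linkerPrefix@scarLength)
  sh <- dnaFragment(linkerSuffix@suffixSeq, lOvh = linkerSuffix@scarLength,
                    rOvh = linkerSuffix@tailLength)
  m1 <- joinFragments(ph, core,
                      sprintf("%s-P half", linkerPrefix@name),
                      core@meta$name %||% "part core")
  clip <- joinFragments(m1, sh, "clip", sprintf("%s-S half", linkerSuffix@name))
  clip@meta <- list(
    part = core@meta$name, prefix = linkerPrefix@name,
    suffix = linkerSuffix@name,
    segLengths = c(
      prefixHalf = nchar(linkerPrefix@prefixSeq),
      core = nchar(core@seq),
      suffixHalf = nchar(linkerSuffix@suffixSeq)),
    tailLength = linkerPrefix@tailLength,
    scarLength = linkerPrefix@scarLength)
  clip
}

## sticky-end join: A's right overhang must equal B's left overhang
joinFragments <- function(a, b, aName = "fragment", bName = "fragment") {
  if (a@rOvh != b@lOvh ||
      rightOverhang(a) != leftOverhang(b))
    stop("ligation-incompatibility error: ", aName, " end '",
         rightOverhang(a), "' does not match ", bName, " end '",
         leftOverhang(b), "'")
  dnaFragment(paste0(a@seq, substring(b@seq, b@lOvh + 1L)),
              lOvh = a@lOvh, rOvh = b@rOvh, meta = a@meta)
}

#' Melt a clip back into its three segments
#'
#' The in-silico inverse of [ligateClip()]: splits a clip at its recorded
#' segment boundaries, returning the prefix half, core and suffix half
#' texts (overhang regions shared between neighbours appear in both, as
#' in the inputs).
#'
#' @param clip a clip [DnaFragment-class] from [ligateClip()].
#' @return list with `prefixHalf`, `core`, `suffixHalf` strings.
#' @export
meltClip <- function(clip) {
  sl <- clip@meta$segLengths
  sc <- clip@meta$scarLength
  if (is.null(sl)) stop("not a clip: no segment metadata")
  n <- nchar(clip@seq)
  list(
    prefixHalf = substr(clip@seq, 1L, sl[["prefixHalf"]]),
    core = substr(clip@seq, sl[["prefixHalf"]] - sc + 1L,
                  sl[["prefixHalf"]] - sc + sl[["core"]]),
    suffixHalf = substring(clip@seq, n - sl[["suffixHalf"]] + 1L))
}

#' Anneal clips into a circular construct
#'
#' Assembly order is recovered from tail complementarity, not from input
#' order: each clip's right 21-base tail must pair with exactly one other
#' clip's left tail. The clips must close a single circle using every clip
#' exactly once.
#'
#' @param clipList list of clip [DnaFragment-class] objects from
#'   [ligateClip()].
#' @param name construct name for the result.
#' @param rotateToPart rotate the circle so this part's core starts at
#'   position 0 (defaults to the part of the first clip given).
#' @return a [PredictedConstruct-class].
#' @export
annealAssembly <- function(clipList, name = "construct",
                           rotateToPart = NULL) {
  n <- length(clipList)
  if (n < 2L) stop("incomplete-assembly error: need at least two clips")
  lTails <- vapply(clipList, leftOverhang, "")
  rTails <- vapply(clipList, rightOverhang, "")
  nxt <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(lTails == rTails[i])
    if (length(hit) == 0L)
      stop("incomplete-assembly error: no clip pairs with the right tail of clip ",
           i, " (", clipList[[i]]@meta$part %||% "?", ")")
    if (length(hit) > 1L)
      stop("ambiguity error: tail of clip ", i,
           " matches several clips (same linker used twice?)")
    nxt[i] <- hit
  }
  if (anyDuplicated(nxt))
    stop("ambiguity error: two clips share a left tail")
  order <- integer(n)
  order[1L] <- 1L
  for (k in 2:n) {
    order[k] <- nxt[order[k - 1L]]
    if (order[k] == 1L)
      stop("incomplete-assembly error: clips form ", k - 1L,
           "-clip circle plus leftovers (multiple disjoint circles)")
  }
  if (nxt[order[n]] != 1L)
    stop("incomplete-assembly error: clips do not close a circle")

  tl <- clipList[[1L]]@meta$tailLength %||% 21L
  segs <- vapply(order, function(i)
    substring(clipList[[i]]@seq, tl + 1L), "")
  circ <- paste(segs, collapse = "")

  # feature bookkeeping: walk the circle clip by clip
  feats <- list()
  pos <- 0L  # 0-based cursor at the start of the first clip's post-tail segment
  sc <- clipList[[1L]]@meta$scarLength %||% 4L
  L <- nchar(circ)
  for (k in seq_len(n)) {
    cl <- clipList[[order[k]]]
    sl <- cl@meta$segLengths
    pCore <- sl[["prefixHalf"]] - tl       # prefix-half beyond its tail (incl scar)
    coreLen <- sl[["core"]]
    sCore <- sl[["suffixHalf"]] - tl       # suffix-half before its tail (incl scar)
    partStart <- pos + pCore - sc          # part core includes its scars
    feats[[length(feats) + 1L]] <- data.frame(
      start = partStart, end = partStart + coreLen,
      type = "part", label = cl@meta$part %||% "part",
      stringsAsFactors = FALSE)
    linkStart <- partStart + coreLen - sc  # linker starts at the shared scar
    linkEnd <- linkStart + sCore + tl +
      (clipList[[nxt[order[k]]]]@meta$segLengths[["prefixHalf"]] - tl)
    feats[[length(feats) + 1L]] <- data.frame(
      start = linkStart, end = linkEnd,
      type = "linker", label = cl@meta$suffix %||% "linker",
      stringsAsFactors = FALSE)
    pos <- pos + (nchar(cl@seq) - tl)
  }
  features <- do.call(rbind, feats)

  # rotate so the requested part core starts at 0; feature spans keep their
  # lengths, starts move modulo the circle length (a feature crossing the
  # origin keeps end > L, denoting the wrap)
  len <- features$end - features$start
  features$start <- features$start %% L
  if (is.null(rotateToPart)) rotateToPart <- clipList[[1L]]@meta$part
  anchor <- which(features$type == "part" & features$label == rotateToPart)
  shift <- if (length(anchor)) features$start[anchor[1L]] else 0L
  if (shift > 0L) {
    circ <- paste0(substring(circ, shift + 1L), substr(circ, 1L, shift))
    features$start <- (features$start - shift) %% L
  }
  features$end <- features$start + len
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  new("PredictedConstruct", name = name, seq = circ,
      features = features, notes = character())
}

#' Verify the idempotent standard on a predicted construct
#'
#' A construct assembled with the methylated Prefix/Suffix-recapitulating
#' linkers (LMP/LMS) must contain regenerated, now-unprotected Prefix and
#' Suffix sites flanking its payload, so that digesting the construct
#' returns the payload — the product is valid input for another assembly
#' round. The report never throws: failures are returned with reasons.
#'
#' @param construct a [PredictedConstruct-class].
#' @param model a [restrictionModel()].
#' @param expectedPayload optional plus-strand payload sequence to compare
#'   the re-digest against.
#' @return list with `pass` (logical), `reasons` (character),
#'   `prefixFound`/`suffixFound` (logical), and `payload` (a
#'   [DnaFragment-class] or NULL).
#' @export
verifyIdempotence <- function(construct, model = restrictionModel(),
                              expectedPayload = NULL) {
  sites <- findRecognitionSites(predictedSeq(construct), model,
                                methyl = integer(), circular = TRUE)
  act <- sites[!sites$protected, , drop = FALSE]
  prefixFound <- sum(act$strand == "+") == 1L
  suffixFound <- sum(act$strand == "-") == 1L
  reasons <- character()
  if (sum(act$strand == "+") == 0L)
    reasons <- c(reasons, "missing-Prefix: no regenerated plus-strand recognition site")
  if (sum(act$strand == "-") == 0L)
    reasons <- c(reasons, "missing-Suffix: no regenerated minus-strand recognition site")
  if (sum(act$strand == "+") > 1L)
    reasons <- c(reasons, "extra plus-strand recognition site(s) outside the regenerated Prefix")
  if (sum(act$strand == "-") > 1L)
    reasons <- c(reasons, "extra minus-strand recognition site(s) outside the regenerated Suffix")
  payload <- NULL
  if (prefixFound && suffixFound) {
    payload <- tryCatch(digestPart(construct, model), error = function(e) {
      reasons <<- c(reasons, conditionMessage(e)); NULL })
    if (!is.null(payload) && !is.null(expectedPayload) &&
        fragmentSeq(payload) != toupper(expectedPayload))
      reasons <- c(reasons, "re-digested payload differs from the expected sequence")
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       prefixFound = prefixFound, suffixFound = suffixFound,
       payload = payload)
}

#' Predict assembled construct sequences for a design set
#'
#' For each design: digest every part from its storage sequence, ligate it
#' to the halves of its flanking linkers (the clip reaction), anneal all
#' clips into the circular construct, and annotate part/linker features.
#' Failures are collected per design without aborting the batch.
#'
#' @param designs list of [ConstructDesign-class].
#' @param partSeqs named list of [PartSequence-class] (stored parts).
#' @param linkerSeqs named list of [LinkerSequence-class].
#' @param model a [restrictionModel()].
#' @param genbankDir optional directory: one annotated GenBank file per
#'   successful design is written there.
#' @return list with `constructs` (named list of
#'   [PredictedConstruct-class]) and `errors` (named character vector of
#'   per-design failure messages).
#' @export
predictConstructs <- function(designs, partSeqs, linkerSeqs,
                              model = restrictionModel(), genbankDir = NULL) {
  constructs <- list()
  errors <- character()
  for (d in designs) {
    res <- tryCatch({
      el <- designElements(d)
      n <- length(el)
      clipsL <- vector("list", n %/% 2L)
      for (k in seq_len(n %/% 2L)) {
        pPos <- 2L * k
        partName <- el[pPos]
        prefixName <- el[pPos - 1L]
        suffixName <- if (pPos + 1L <= n) el[pPos + 1L] else el[1L]
        ps <- partSeqs[[partName]]
        if (is.null(ps))
          stop("missing-sequence error: no stored sequence for part '",
               partName, "'")
        for (ln in c(prefixName, suffixName))
          if (is.null(linkerSeqs[[ln]]))
            stop("missing-sequence error: no sequence for linker '", ln, "'")
        core <- digestPart(ps, model)
        clipsL[[k]] <- ligateClip(core, linkerSeqs[[prefixName]],
                                  linkerSeqs[[suffixName]])
      }
      pc <- annealAssembly(clipsL, name = designName(d),
                           rotateToPart = el[2L])
      pc@notes <- straySiteNotes(pc, linkerSeqs, model)
      pc
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[designName(d)] <- conditionMessage(res)
    } else {
      constructs[[designName(d)]] <- res
      if (!is.null(genbankDir)) {
        if (!dir.exists(genbankDir)) dir.create(genbankDir, recursive = TRUE)
        writeGenbankRecord(
          designName(d), predictedSeq(res),
          file.path(genbankDir, paste0(designName(d), ".gb")),
          circular = TRUE, features = constructFeatures(res),
          definition = sprintf("predicted BASIC assembly (%d bp)",
                               nchar(predictedSeq(res))))
      }
    }
  }
  list(constructs = constructs, errors = errors)
}

## flag unprotected recognition sites lying outside the features of
## methylated (Prefix/Suffix-recapitulating) linkers
straySiteNotes <- function(construct, linkerSeqs, model) {
  sites <- findRecognitionSites(predictedSeq(construct), model,
                                circular = TRUE)
  if (!nrow(sites)) return(character())
  f <- constructFeatures(construct)
  methylated <- vapply(linkerSeqs, function(l) l@methylated, TRUE)
  lmFeats <- f[f$type == "linker" & f$label %in% names(methylated)[methylated], ,
               drop = FALSE]
  L <- nchar(predictedSeq(construct))
  inLm <- vapply(sites$pos, function(p) {
    p0 <- p - 1L  # 0-based
    any((p0 >= lmFeats$start & p0 < lmFeats$end) |
        (p0 + L >= lmFeats$start & p0 + L < lmFeats$end))
  }, TRUE)
  stray <- sites[!inLm, , drop = FALSE]
  if (!nrow(stray)) return(character())
  sprintf("unprotected recognition site outside regenerated Prefix/Suffix at %d (%s)",
          stray$pos, stray$strand)
}

#' Read and write linker sequence configurations
#'
#' The linker set is data, not constants: sequences load from a JSON or
#' YAML file with one entry per linker: `name`, `prefixSeq`, `suffixSeq`,
#' optional `tailLength` (21), `scarLength` (4), `methylated` (false).
#'
#' @param file path to a `.json`, `.yaml` or `.yml` file.
#' @return named list of [LinkerSequence-class].
#' @export
readLinkerConfig <- function(file) {
  raw <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::read_yaml(file)
  else jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  out <- lapply(raw, function(x)
    linkerSequence(x$name, x$prefixSeq, x$suffixSeq,
                   tailLength = x$tailLength %||% 21L,
                   scarLength = x$scarLength %||% 4L,
                   methylated = isTRUE(x$methylated)))
  names(out) <- vapply(out, function(l) l@name, "")
  out
}

#' @rdname readLinkerConfig
#' @param linkerSeqs named list of [LinkerSequence-class].
#' @export
writeLinkerConfig <- function(linkerSeqs, file) {
  raw <- unname(lapply(linkerSeqs, function(l) list(
    name = l@name, prefixSeq = l@prefixSeq, suffixSeq = l@suffixSeq,
    tailLength = l@tailLength, scarLength = l@scarLength,
    methylated = l@methylated)))
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::write_yaml(raw, file)
  else writeLines(jsonlite::toJSON(raw, auto_unbox = TRUE, pretty = TRUE), file)
  invisible(file)
}
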