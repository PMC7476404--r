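#' @import methods
NULL

## ---------------------------------------------------------------------------
## Design vocabulary
## ---------------------------------------------------------------------------

#' ConstructDesign: one BASIC construct as an alternation of linkers and parts
#'
#' A construct design is an ordered, circular alternation of linker and part
#' names starting with a linker: `linker, part, linker, part, ...`; the
#' element after the last part wraps around to the first linker. Odd
#' positions are linkers, even positions are parts.
#'
#' @slot name construct identifier, unique within a design set.
#' @slot well destination well for the assembled construct ("A1" style).
#' @slot elements character vector of element names, alternating
#'   linker/part, length even and >= 4.
#' @exportClass ConstructDesign
setClass("ConstructDesign",
  representation(name = "character", well = "character", elements = "character"))

setValidity("ConstructDesign", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@well) != 1L || !is_well(object@well))
    msg <- c(msg, "well must be a single valid well address")
  n <- length(object@elements)
  if (n < 4L || n %% 2L != 0L)
    msg <- c(msg, "elements must alternate linker/part with even length >= 4")
  if (any(!nzchar(trimws(object@elements))))
    msg <- c(msg, "element names must be non-empty")
  lnk <- object@elements[seq(1L, n, by = 2L)]
  if (anyDuplicated(lnk))
    msg <- c(msg, sprintf("linker(s) used twice in one design: %s",
                          paste(unique(lnk[duplicated(lnk)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Create a construct design
#'
#' @param name construct name.
#' @param well destination well, e.g. `"A1"`.
#' @param elements character vector alternating linker and part names,
#'   beginning with a linker (circular: the last part joins back to the
#'   first linker).
#' @return a [ConstructDesign-class] object.
#' @examples
#' constructDesign("toy", "A1", c("LMS", "backbone", "LMP", "insert"))
#' @export
constructDesign <- function(name, well, elements) {
  new("ConstructDesign", name = as.character(name),
      well = wellAddress(well), elements = trimws(as.character(elements)))
}

#' PlateMap: reagent name to well mapping for one 96-well source plate
#'
#' @slot plateId text label of the plate.
#' @slot kind `"part"` or `"linker"`. Linker plates hold half-linkers named
#'   `<linker>-P` (prefix half) and `<linker>-S` (suffix half).
#' @slot entries named character vector: reagent name -> well address.
#' @exportClass PlateMap
setClass("PlateMap",
  representation(plateId = "character", kind = "character", entries = "character"))

setValidity("PlateMap", function(object) {
  msg <- character()
  if (length(object@plateId) != 1L) msg <- c(msg, "plateId must be a single string")
  if (length(object@kind) != 1L || !object@kind %in% c("part", "linker"))
    msg <- c(msg, "kind must be 'part' or 'linker'")
  nm <- names(object@entries)
  if (length(object@entries) > 0L) {
    if (is.null(nm) || any(!nzchar(nm)))
      msg <- c(msg, "all entries must be named with non-empty reagent names")
    if (anyDuplicated(nm))
      msg <- c(msg, sprintf("duplicate reagent name(s): %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (!all(vapply(object@entries, is_well, TRUE)))
      msg <- c(msg, "all wells must be valid 96-well addresses")
    if (anyDuplicated(object@entries))
      msg <- c(msg, sprintf("two reagents share well(s): %s",
                            paste(unique(object@entries[duplicated(object@entries)]),
                                  collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Create a plate map
#'
#' @param plateId plate label.
#' @param entries named character vector, reagent name -> well.
#' @param kind `"part"` or `"linker"`.
#' @return a [PlateMap-class].
#' @export
plateMap <- function(plateId, entries, kind = c("part", "linker")) {
  kind <- match.arg(kind)
  ent <- wellAddress(entries)
  names(ent) <- trimws(names(entries))
  new("PlateMap", plateId = as.character(plateId), kind = kind, entries = ent)
}

## ---------------------------------------------------------------------------
## Step-1 planning
## ---------------------------------------------------------------------------

#' ClipPlan: the deduplicated clip reactions implied by a design set
#'
#' A clip is the (prefix linker, part, suffix linker) triple obtained by
#' walking a design's circular alternation: each part yields one clip with
#' the linker before it and the linker after it. Clips are deduplicated
#' across all designs by the full triple, first-seen order preserved.
#'
#' @slot clips data.frame with columns `prefix`, `part`, `suffix`, one row
#'   per unique clip, in first-occurrence order.
#' @slot wells character vector of clip-reaction wells (columns 1-6,
#'   column-major), length 0 until [assignClipWells()] is called.
#' @slot constructRefs named list: construct name -> integer indices into
#'   `clips`, in the construct's part order.
#' @slot volumes data.frame of per-clip reagent volumes (0 rows until
#'   [computeClipVolumes()] fills it).
#' @exportClass ClipPlan
setClass("ClipPlan",
  representation(clips = "data.frame", wells = "character",
                 constructRefs = "list", volumes = "data.frame"))

setValidity("ClipPlan", function(object) {
  msg <- character()
  need <- c("prefix", "part", "suffix")
  if (!all(need %in% names(object@clips)))
    msg <- c(msg, "clips must have columns prefix, part, suffix")
  else {
    key <- do.call(paste, c(object@clips[need], sep = "\r"))
    if (anyDuplicated(key)) msg <- c(msg, "clips must be unique triples")
  }
  nclip <- nrow(object@clips)
  if (length(object@wells) > 0L) {
    if (length(object@wells) != nclip)
      msg <- c(msg, "wells must have one entry per clip")
    else if (any(wellColumn(object@wells) > 6L))
      msg <- c(msg, "clip wells are restricted to columns 1-6")
  }
  bad <- vapply(object@constructRefs,
                function(i) any(i < 1L | i > nclip), TRUE)
  if (any(bad))
    msg <- c(msg, "constructRefs must index into the clip table")
  if (length(msg)) msg else TRUE
})

#' MasterMixRecipe: the Step-1 clip-reaction master mix
#'
#' Per 20 ul of mix (one reaction): 3 ul 10x ligase buffer, 1 ul BsaI,
#' 0.5 ul T4 DNA ligase, 15.5 ul water. Totals scale linearly with the
#' reaction count and an excess fraction for dead volume.
#'
#' @slot perReaction named numeric, ul per reaction (sums to 20).
#' @slot nReactions number of clip reactions.
#' @slot excessFraction dimensionless excess (>= 0) applied to totals.
#' @slot totals named numeric, ul per component for the whole mix.
#' @exportClass MasterMixRecipe
setClass("MasterMixRecipe",
  representation(perReaction = "numeric", nReactions = "integer",
                 excessFraction = "numeric", totals = "numeric"))

setValidity("MasterMixRecipe", function(object) {
  msg <- character()
  if (abs(sum(object@perReaction) - 20) > 1e-9)
    msg <- c(msg, "per-reaction components must sum to exactly 20 ul")
  if (object@nReactions < 1L) msg <- c(msg, "nReactions must be >= 1")
  if (object@excessFraction < 0) msg <- c(msg, "excessFraction must be >= 0")
  expect <- object@perReaction * object@nReactions * (1 + object@excessFraction)
  if (max(abs(object@totals - expect)) > 1e-9)
    msg <- c(msg, "totals must equal perReaction * n * (1 + excess)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Step 2-4 planning
## ---------------------------------------------------------------------------

#' PurificationPlan: SPRI bead cleanup of clip reactions (Step 2)
#'
#' Each raw clip in the left half-plate (columns 1-6) is purified in place
#' and its eluate deposited in the mirror well of the right half-plate:
#' same row, column + 6.
#'
#' @slot mapping data.frame with columns `sourceWell`, `destWell`.
#' @slot params list of volumes/timings: `beadVolume` (54 ul),
#'   `ethanolVolume` (150 ul of 70\% ethanol), `nWashes`, `elutionVolume`
#'   (resuspension water, >= 38), `elutantVolume` (38 ul transferred out),
#'   plus bind/settle/dry times in seconds.
#' @exportClass PurificationPlan
setClass("PurificationPlan",
  representation(mapping = "data.frame", params = "list"))

setValidity("PurificationPlan", function(object) {
  msg <- character()
  m <- object@mapping
  if (!all(c("sourceWell", "destWell") %in% names(m)))
    return("mapping needs sourceWell and destWell columns")
  if (nrow(m) > 0L) {
    if (any(wellColumn(m$sourceWell) > 6L))
      msg <- c(msg, "source wells must lie in columns 1-6")
    ok <- wellRow(m$destWell) == wellRow(m$sourceWell) &
      wellColumn(m$destWell) == wellColumn(m$sourceWell) + 6L
    if (!all(ok))
      msg <- c(msg, "destination must mirror source: same row, column + 6")
  }
  p <- object@params
  if (!is.null(p$elutionVolume) && !is.null(p$elutantVolume) &&
      p$elutionVolume < p$elutantVolume)
    msg <- c(msg, "elutionVolume must be >= the transferred elutant volume")
  if (length(msg)) msg else TRUE
})

#' AssemblyPlan: annealing assembly of purified clips (Step 3)
#'
#' Every construct is assembled in exactly `totalVolume` (15 ul): `clipVolume`
#' (1.5 ul) from each purified-clip well plus annealing buffer to volume.
#'
#' @slot transfers data.frame with columns `construct`, `destWell`, `source`
#'   (`"purified_clip"` or `"annealing_buffer"`), `sourceWell` (NA for
#'   buffer), `volume`.
#' @slot totalVolume assembly volume per well, ul.
#' @slot clipVolume volume per purified clip, ul.
#' @exportClass AssemblyPlan
setClass("AssemblyPlan",
  representation(transfers = "data.frame", totalVolume = "numeric",
                 clipVolume = "numeric"))

setValidity("AssemblyPlan", function(object) {
  tr <- object@transfers
  need <- c("construct", "destWell", "source", "sourceWell", "volume")
  if (!all(need %in% names(tr)))
    return("transfers needs construct, destWell, source, sourceWell, volume")
  msg <- character()
  if (nrow(tr) > 0L) {
    tot <- tapply(tr$volume, tr$destWell, sum)
    if (any(abs(tot - object@totalVolume) > 1e-9))
      msg <- c(msg, sprintf("every assembly well must total exactly %g ul",
                            object@totalVolume))
    if (any(tr$volume <= 0))
      msg <- c(msg, "all transfer volumes must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' TransformationPlan: heat-shock transformation and agar spotting (Step 4)
#'
#' @slot wells data.frame, one row per transformation: `label`, `well`,
#'   `role` (`"construct"`, `"backbone_control"`, `"no_plasmid_control"`),
#'   `assemblyWell` (NA for controls without DNA), `cellVolume`,
#'   `dnaVolume`, `socVolume`.
#' @slot spots data.frame: `label`, `well`, `tray`, `gridWell`, `volume`.
#'   One agar tray per spot volume; grid coordinates mirror the
#'   transformation plate (8 x 12, 9 mm pitch).
#' @slot params list: `spotVolumes`, `controlsEnabled`, `heatShock` prompt
#'   text, recovery time/temperature.
#' @exportClass TransformationPlan
setClass("TransformationPlan",
  representation(wells = "data.frame", spots = "data.frame", params = "list"))

setValidity("TransformationPlan", function(object) {
  msg <- character()
  w <- object@wells
  if (nrow(w) > 0L && anyDuplicated(w$well))
    msg <- c(msg, "transformation wells must be unique")
  s <- object@spots
  if (nrow(s) > 0L) {
    key <- paste(s$tray, s$gridWell)
    if (anyDuplicated(key))
      msg <- c(msg, "no two spots may share a grid coordinate on one tray")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Instruction scripts
## ---------------------------------------------------------------------------

TRANSFER_VERBS <- c("aspirate", "dispense", "transfer")
DEVICE_VERBS <- c("engage_magnet", "disengage_magnet", "delay",
                  "set_temperature", "prompt_user", "comment", "mix")

#' Script: an ordered instruction stream for one BASIC step
#'
#' The machine-readable analogue of one generated robot script: a
#' deterministic sequence of atomic liquid-handling and device actions,
#' plus the deck layout and meta-information (master-mix recipe, prompts,
#' provenance digests).
#'
#' Instruction columns: `verb` (one of aspirate, dispense, transfer, mix,
#' engage_magnet, disengage_magnet, delay, set_temperature, prompt_user,
#' comment), `sourceLabware`/`sourceWell`, `destLabware`/`destWell`,
#' `volume` (ul; transfer verbs only), `tipPolicy` (`fresh_tip` or
#' `reuse_tip`), `temperature` (deg C), `seconds`, `mixReps`, `message`.
#'
#' @slot stepId integer 1-4.
#' @slot deckLayout named character: deck-slot label -> labware label.
#' @slot instructions data.frame as described above.
#' @slot metadata list (recipes, prompts, provenance, config echo).
#' @exportClass Script
setClass("Script",
  representation(stepId = "integer", deckLayout = "character",
                 instructions = "data.frame", metadata = "list"))

setValidity("Script", function(object) {
  msg <- character()
  if (!object@stepId %in% 1:4) msg <- c(msg, "stepId must be 1-4")
  ins <- object@instructions
  need <- c("verb", "sourceLabware", "sourceWell", "destLabware", "destWell",
            "volume", "tipPolicy", "temperature", "seconds", "mixReps", "message")
  if (!all(need %in% names(ins)))
    return(paste("instructions must have columns:", paste(need, collapse = ", ")))
  if (nrow(ins) > 0L) {
    if (!all(ins$verb %in% c(TRANSFER_VERBS, DEVICE_VERBS)))
      msg <- c(msg, "unknown instruction verb(s)")
    tr <- ins$verb %in% TRANSFER_VERBS
    if (any(tr & (is.na(ins$volume) | ins$volume <= 0)))
      msg <- c(msg, "transfer verbs must carry volume > 0")
    if (any(tr & (is.na(ins$destLabware) | is.na(ins$destWell))))
      msg <- c(msg, "transfer verbs must carry a destination")
    dev <- ins$verb %in% setdiff(DEVICE_VERBS, "mix")
    if (any(dev & !is.na(ins$volume)))
      msg <- c(msg, "device verbs must not carry a volume")
    used <- unique(stats::na.omit(c(ins$sourceLabware, ins$destLabware)))
    if (!all(used %in% object@deckLayout))
      msg <- c(msg, sprintf("labware not in deck layout: %s",
                            paste(setdiff(used, object@deckLayout), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Sequence model
## ---------------------------------------------------------------------------

#' DnaFragment: a double-stranded DNA fragment with sticky ends
#'
#' Fragments are written on the plus strand. The first `lOvh` bases are a
#' single-stranded 5' extension of the top strand; the last `rOvh` bases
#' are (the plus-strand rendering of) a single-stranded 5' extension of the
#' bottom strand. Two fragments ligate/anneal when the right overhang text
#' of the first equals the left overhang text of the second.
#'
#' @slot seq plus-strand sequence (A/C/G/T).
#' @slot lOvh,rOvh integer overhang lengths at the left/right end.
#' @slot meta list of bookkeeping (segment labels and lengths).
#' @exportClass DnaFragment
setClass("DnaFragment",
  representation(seq = "character", lOvh = "integer", rOvh = "integer",
                 meta = "list"))

setValidity("DnaFragment", function(object) {
  msg <- character()
  if (length(object@seq) != 1L || grepl("[^ACGT]", object@seq))
    msg <- c(msg, "seq must be a single A/C/G/T string")
  if (object@lOvh < 0L || object@rOvh < 0L)
    msg <- c(msg, "overhang lengths must be >= 0")
  if (object@lOvh + object@rOvh > nchar(object@seq))
    msg <- c(msg, "overhangs cannot exceed the sequence length")
  if (length(msg)) msg else TRUE
})

dnaFragment <- function(seq, lOvh = 0L, rOvh = 0L, meta = list()) {
  new("DnaFragment", seq = toupper(as.character(seq)),
      lOvh = as.integer(lOvh), rOvh = as.integer(rOvh), meta = meta)
}

#' PartSequence: a stored BASIC part
#'
#' A stored part sits in a (usually circular) storage vector, flanked by the
#' standard Prefix and Suffix sequences whose BsaI sites release the part
#' core with its two 4-nt scar overhangs. Methylation marks (C-5 methyl
#' positions) protect any recognition site they fall inside.
#'
#' @slot name part name.
#' @slot seq plus-strand sequence of the stored molecule.
#' @slot topology `"circular"` or `"linear"`.
#' @slot methyl integer positions (1-based) of methyl marks.
#' @exportClass PartSequence
setClass("PartSequence",
  representation(name = "character", seq = "character", topology = "character",
                 methyl = "integer"))

setValidity("PartSequence", function(object) {
  msg <- character()
  if (grepl("[^ACGT]", object@seq))
    msg <- c(msg, "sequence alphabet must be A/C/G/T")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  if (length(object@methyl) &&
      any(object@methyl < 1L | object@methyl > nchar(object@seq)))
    msg <- c(msg, "methyl positions must lie within the sequence")
  if (length(msg)) msg else TRUE
})

#' Create a stored part sequence
#' @param name part name.
#' @param seq plus-strand sequence (A/C/G/T; upper-cased on input).
#' @param topology `"circular"` (storage vector) or `"linear"`.
#' @param methyl integer vector of methyl-mark positions (1-based).
#' @return a [PartSequence-class].
#' @export
partSequence <- function(name, seq, topology = c("circular", "linear"),
                         methyl = integer()) {
  topology <- match.arg(topology)
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGT]", seq))
    stop("alphabet error: part '", name, "' contains non-ACGT characters")
  new("PartSequence", name = as.character(name), seq = seq,
      topology = topology, methyl = as.integer(methyl))
}

#' LinkerSequence: the two halves of a BASIC linker
#'
#' Each half-linker carries a 4-nt scar overhang that ligates to a part end
#' and a 21-base single-stranded tail that directs assembly. The prefix
#' (P-) half ligates upstream of a part (at its Prefix end); the suffix
#' (S-) half ligates downstream (at its Suffix end). Written on the plus
#' strand, the suffix half's right tail and the prefix half's left tail are
#' the same 21-mer text (physically, reverse-complementary single strands),
#' so the full linker re-forms when clips anneal.
#'
#' @slot name linker name.
#' @slot prefixSeq plus-strand text of the P- half:
#'   `tail(21) + core + scar(4)`.
#' @slot suffixSeq plus-strand text of the S- half:
#'   `scar(4) + core + tail(21)`.
#' @slot tailLength,scarLength integers (21 and 4 by default).
#' @slot methylated flag: TRUE for the methylated Prefix/Suffix-
#'   recapitulating linkers (LMP/LMS) whose embedded BsaI sites are
#'   protected during assembly.
#' @exportClass LinkerSequence
setClass("LinkerSequence",
  representation(name = "character", prefixSeq = "character",
                 suffixSeq = "character", tailLength = "integer",
                 scarLength = "integer", methylated = "logical"))

setValidity("LinkerSequence", function(object) {
  msg <- character()
  if (grepl("[^ACGT]", object@prefixSeq) || grepl("[^ACGT]", object@suffixSeq))
    msg <- c(msg, "linker sequences must be A/C/G/T")
  tl <- object@tailLength; sl <- object@scarLength
  if (nchar(object@prefixSeq) < tl + sl || nchar(object@suffixSeq) < tl + sl)
    msg <- c(msg, "each half must be at least tail + scar long")
  else {
    pTail <- substr(object@prefixSeq, 1L, tl)
    sTail <- substring(object@suffixSeq, nchar(object@suffixSeq) - tl + 1L)
    if (pTail != sTail)
      msg <- c(msg, "the two halves' tails must re-form the linker (identical plus-strand text)")
  }
  if (length(msg)) msg else TRUE
})

#' Create a linker sequence record
#' @param name linker name.
#' @param prefixSeq,suffixSeq plus-strand half sequences (see
#'   [LinkerSequence-class] for layout).
#' @param tailLength single-stranded tail length (21).
#' @param scarLength scar overhang length (4).
#' @param methylated TRUE for methylated LMP/LMS-style linkers.
#' @return a [LinkerSequence-class].
#' @export
linkerSequence <- function(name, prefixSeq, suffixSeq, tailLength = 21L,
                           scarLength = 4L, methylated = FALSE) {
  new("LinkerSequence", name = as.character(name),
      prefixSeq = toupper(prefixSeq), suffixSeq = toupper(suffixSeq),
      tailLength = as.integer(tailLength), scarLength = as.integer(scarLength),
      methylated = isTRUE(methylated))
}

#' PredictedConstruct: the simulated circular sequence of an assembly
#'
#' @slot name construct name.
#' @slot seq circular plus-strand sequence, rotated so the design's first
#'   part core starts at position 0.
#' @slot features data.frame: `start`, `end` (0-based half-open, plus
#'   strand), `type` (`"part"`/`"linker"`), `label`. Features tile the
#'   circle; adjacent features share their 4-nt scar junctions.
#' @slot notes character vector of flags (e.g. stray unprotected
#'   recognition sites outside the regenerated Prefix/Suffix).
#' @exportClass PredictedConstruct
setClass("PredictedConstruct",
  representation(name = "character", seq = "character",
                 features = "data.frame", notes = "character"))

setValidity("PredictedConstruct", function(object) {
  msg <- character()
  if (grepl("[^ACGT]", object@seq)) msg <- c(msg, "sequence must be A/C/G/T")
  f <- object@features
  if (nrow(f) > 0L) {
    if (!all(c("start", "end", "type", "label") %in% names(f)))
      msg <- c(msg, "features need start, end, type, label")
    else if (any(f$start < 0L) || any(f$start >= f$end))
      msg <- c(msg, "feature coordinates must be 0-based half-open with start < end")
  }
  if (length(msg)) msg else TRUE
})
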