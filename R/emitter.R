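## Instruction-stream emission: compiles step plans into ordered Script
## objects, the machine-readable analogue of the four generated robot
## scripts, plus picklist / protocol / robot-script renderings.

emptyInstructions <- function() {
  data.frame(verb = character(), sourceLabware = character(),
             sourceWell = character(), destLabware = character(),
             destWell = character(), volume = numeric(),
             tipPolicy = character(), temperature = numeric(),
             seconds = numeric(), mixReps = numeric(), message = character(),
             stringsAsFactors = FALSE)
}

insRow <- function(verb, sourceLabware = NA_character_, sourceWell = NA_character_,
                   destLabware = NA_character_, destWell = NA_character_,
                   volume = NA_real_, tipPolicy = NA_character_,
                   temperature = NA_real_, seconds = NA_real_,
                   mixReps = NA_real_, message = NA_character_) {
  data.frame(verb = verb, sourceLabware = sourceLabware,
             sourceWell = sourceWell, destLabware = destLabware,
             destWell = destWell, volume = volume, tipPolicy = tipPolicy,
             temperature = temperature, seconds = seconds, mixReps = mixReps,
             message = message, stringsAsFactors = FALSE)
}

insTransfer <- function(srcLab, srcWell, dstLab, dstWell, volume, tip) {
  insRow("transfer", srcLab, srcWell, dstLab, dstWell, volume, tip)
}

insAspirate <- function(srcLab, srcWell, dstLab, volume, tip) {
  insRow("aspirate", srcLab, srcWell, dstLab, "waste", volume, tip)
}

bindIns <- function(rows) {
  rows <- Filter(function(x) !is.null(x) && nrow(x) > 0L, rows)
  if (!length(rows)) return(emptyInstructions())
  do.call(rbind, rows)
}

#' Compile a step plan into an instruction script
#'
#' Dispatches on the plan class: a [ClipPlan-class] yields the Step-1
#' (clip-reaction setup) script, a [PurificationPlan-class] Step 2, an
#' [AssemblyPlan-class] Step 3 and a [TransformationPlan-class] Step 4.
#' Every planned transfer is realised exactly once; user prompts are
#' inserted where a manual action (thermocycler run, heat shock) is
#' required. Emission is deterministic: the same plan always yields the
#' identical script.
#'
#' Tip policy: a fresh tip for every DNA-bearing transfer (distinct liquid
#' and destination), tip reuse within a single clean-reagent distribution
#' (water, master mix, ethanol, buffer); recorded per instruction.
#'
#' @param plan a step plan object.
#' @param partPlate,linkerPlate source-plate maps (Step 1 only).
#' @param recipe a [MasterMixRecipe-class] for the Step-1 metadata.
#' @param config configuration list.
#' @param provenance optional named list recorded in the metadata (input
#'   digests, package version).
#' @param ... passed through to methods.
#' @return a [Script-class].
#' @export
setGeneric("emitScript", function(plan, ...) standardGeneric("emitScript"))

#' @rdname emitScript
#' @export
setMethod("emitScript", "ClipPlan",
function(plan, partPlate, linkerPlate, recipe = NULL,
         config = basicConfig(), provenance = list()) {
  if (ncol(clipVolumes(plan)) == 0L)
    plan <- computeClipVolumes(plan, config)
  if (nrow(clips(plan)) > 0L && !length(plan@wells))
    stop("assign clip wells before emitting the Step-1 script")
  cl <- clips(plan)
  vols <- clipVolumes(plan)
  wells <- plan@wells
  fresh <- config$tips$dnaPolicy
  reuse <- config$tips$reagentPolicy
  if (is.null(recipe) && nrow(cl) > 0L)
    recipe <- masterMixRecipe(nrow(cl), config$clip$excessFraction, config)

  rows <- list(insRow("comment",
    message = sprintf("Step 1: set up %d clip reactions (30 ul each)", nrow(cl))))
  for (i in seq_len(nrow(cl)))
    if (vols$water[i] > 0)
      rows[[length(rows) + 1L]] <- insTransfer(
        "reagents", "water", "clip_plate", wells[i], vols$water[i], reuse)
  for (i in seq_len(nrow(cl)))
    rows[[length(rows) + 1L]] <- insTransfer(
      "reagents", "master_mix", "clip_plate", wells[i], vols$master_mix[i], reuse)
  for (i in seq_len(nrow(cl))) {
    rows[[length(rows) + 1L]] <- insTransfer(
      "linker_plate", reagentWell(linkerPlate, paste0(cl$prefix[i], "-P")),
      "clip_plate", wells[i], vols$prefix_half[i], fresh)
    rows[[length(rows) + 1L]] <- insTransfer(
      "part_plate", reagentWell(partPlate, cl$part[i]),
      "clip_plate", wells[i], vols$part[i], fresh)
    rows[[length(rows) + 1L]] <- insTransfer(
      "linker_plate", reagentWell(linkerPlate, paste0(cl$suffix[i], "-S")),
      "clip_plate", wells[i], vols$suffix_half[i], fresh)
  }
  rows[[length(rows) + 1L]] <- insRow("prompt_user",
    message = paste("Seal the clip plate and run the clip reaction on an",
                    "external thermocycler:", config$clip$thermocycle))
  planned <- stats::setNames(rowSums(vols), wells)
  meta <- list(
    step = "clip_reactions",
    masterMix = if (!is.null(recipe)) list(
      perReaction = as.list(recipe@perReaction),
      nReactions = recipe@nReactions,
      excessFraction = recipe@excessFraction,
      totals = as.list(recipe@totals)) else NULL,
    clipWells = if (nrow(cl)) data.frame(cl, well = wells) else cl,
    plannedWellVolumes = as.list(planned),
    thermocycle = config$clip$thermocycle,
    provenance = provenance)
  new("Script", stepId = 1L,
      deckLayout = c(slot_1 = "clip_plate", slot_2 = "part_plate",
                     slot_3 = "linker_plate", slot_4 = "reagents"),
      instructions = bindIns(rows), metadata = meta)
})

#' @rdname emitScript
#' @export
setMethod("emitScript", "PurificationPlan",
function(plan, config = basicConfig(), provenance = list()) {
  p <- planParams(plan)
  m <- planMapping(plan)
  fresh <- config$tips$dnaPolicy
  reuse <- config$tips$reagentPolicy
  raw <- config$clip$totalVolume
  rows <- list(insRow("comment",
    message = sprintf("Step 2: SPRI purification of %d clip reactions", nrow(m))))
  for (i in seq_len(nrow(m))) {
    rows[[length(rows) + 1L]] <- insTransfer(
      "reagents", "beads", "clip_plate", m$sourceWell[i], p$beadVolume, fresh)
    rows[[length(rows) + 1L]] <- insRow("mix", destLabware = "clip_plate",
      destWell = m$sourceWell[i], mixReps = 10, tipPolicy = fresh)
  }
  rows[[length(rows) + 1L]] <- insRow("delay", seconds = p$bindSeconds,
    message = "bead binding")
  rows[[length(rows) + 1L]] <- insRow("engage_magnet", destLabware = "clip_plate")
  rows[[length(rows) + 1L]] <- insRow("delay", seconds = p$settleSeconds,
    message = "bead settling")
  for (i in seq_len(nrow(m)))
    rows[[length(rows) + 1L]] <- insAspirate(
      "clip_plate", m$sourceWell[i], "waste", raw + p$beadVolume, fresh)
  for (w in seq_len(p$nWashes)) {
    for (i in seq_len(nrow(m)))
      rows[[length(rows) + 1L]] <- insTransfer(
        "reagents", "ethanol_70pct", "clip_plate", m$sourceWell[i],
        p$ethanolVolume, reuse)
    for (i in seq_len(nrow(m)))
      rows[[length(rows) + 1L]] <- insAspirate(
        "clip_plate", m$sourceWell[i], "waste", p$ethanolVolume, fresh)
  }
  rows[[length(rows) + 1L]] <- insRow("delay", seconds = p$drySeconds,
    message = "bead drying")
  rows[[length(rows) + 1L]] <- insRow("disengage_magnet",
    destLabware = "clip_plate")
  for (i in seq_len(nrow(m))) {
    rows[[length(rows) + 1L]] <- insTransfer(
      "reagents", "water", "clip_plate", m$sourceWell[i],
      p$elutionVolume, fresh)
    rows[[length(rows) + 1L]] <- insRow("mix", destLabware = "clip_plate",
      destWell = m$sourceWell[i], mixReps = 10, tipPolicy = fresh)
  }
  rows[[length(rows) + 1L]] <- insRow("delay", seconds = p$bindSeconds,
    message = "elution")
  rows[[length(rows) + 1L]] <- insRow("engage_magnet", destLabware = "clip_plate")
  rows[[length(rows) + 1L]] <- insRow("delay", seconds = p$settleSeconds,
    message = "bead settling")
  for (i in seq_len(nrow(m)))
    rows[[length(rows) + 1L]] <- insTransfer(
      "clip_plate", m$sourceWell[i], "clip_plate", m$destWell[i],
      p$elutantVolume, fresh)
  meta <- list(step = "purification", mirror = m, params = p,
               plannedElutant = stats::setNames(
                 rep(p$elutantVolume, nrow(m)), m$destWell),
               provenance = provenance)
  new("Script", stepId = 2L,
      deckLayout = c(magdeck = "clip_plate", slot_2 = "reagents",
                     slot_3 = "waste"),
      instructions = bindIns(rows), metadata = meta)
})

#' @rdname emitScript
#' @export
setMethod("emitScript", "AssemblyPlan",
function(plan, config = basicConfig(), provenance = list()) {
  tr <- assemblyTransfers(plan)
  fresh <- config$tips$dnaPolicy
  reuse <- config$tips$reagentPolicy
  rows <- list(insRow("comment",
    message = sprintf("Step 3: assemble %d constructs in %g ul each",
                      length(unique(tr$construct)), plan@totalVolume)))
  buf <- tr[tr$source == "annealing_buffer", ]
  for (i in seq_len(nrow(buf)))
    rows[[length(rows) + 1L]] <- insTransfer(
      "reagents", "annealing_buffer", "assembly_plate", buf$destWell[i],
      buf$volume[i], reuse)
  cl <- tr[tr$source == "purified_clip", ]
  for (i in seq_len(nrow(cl)))
    rows[[length(rows) + 1L]] <- insTransfer(
      "clip_plate", cl$sourceWell[i], "assembly_plate", cl$destWell[i],
      cl$volume[i], fresh)
  rows[[length(rows) + 1L]] <- insRow("prompt_user",
    message = paste("Seal the assembly plate and anneal on an external",
                    "thermocycler:", config$assembly$anneal))
  planned <- tapply(tr$volume, tr$destWell, sum)
  meta <- list(step = "assembly",
               plannedWellVolumes = as.list(planned),
               buffer = config$assembly$buffer,
               provenance = provenance)
  new("Script", stepId = 3L,
      deckLayout = c(slot_1 = "assembly_plate", slot_2 = "clip_plate",
                     slot_3 = "reagents"),
      instructions = bindIns(rows), metadata = meta)
})

#' @rdname emitScript
#' @export
setMethod("emitScript", "TransformationPlan",
function(plan, config = basicConfig(), provenance = list()) {
  w <- transformationWells(plan)
  s <- spotPlan(plan)
  p <- planParams(plan)
  fresh <- config$tips$dnaPolicy
  rows <- list(
    insRow("comment", message = sprintf(
      "Step 4: transform %d wells and spot %d spots", nrow(w), nrow(s))),
    insRow("prompt_user", message = paste(
      "Place the competent-cell plate (cells pre-aliquoted per well) on",
      "the temperature module")),
    insRow("set_temperature", destLabware = "transformation_plate",
           temperature = p$setupTemperature))
  for (i in seq_len(nrow(w))) {
    if (w$role[i] == "construct") {
      rows[[length(rows) + 1L]] <- insTransfer(
        "assembly_plate", w$assemblyWell[i], "transformation_plate",
        w$well[i], w$dnaVolume[i], fresh)
    } else if (w$role[i] == "backbone_control") {
      rows[[length(rows) + 1L]] <- insTransfer(
        "reagents", "backbone_plasmid", "transformation_plate",
        w$well[i], w$dnaVolume[i], fresh)
    }
  }
  rows[[length(rows) + 1L]] <- insRow("prompt_user", message = p$heatShock)
  for (i in seq_len(nrow(w)))
    rows[[length(rows) + 1L]] <- insTransfer(
      "reagents", "soc", "transformation_plate", w$well[i],
      w$socVolume[i], fresh)
  rows[[length(rows) + 1L]] <- insRow("set_temperature",
    destLabware = "transformation_plate", temperature = p$recoveryTemperature)
  rows[[length(rows) + 1L]] <- insRow("delay",
    seconds = p$recoverySeconds, message = "SOC recovery")
  for (v in sort(unique(s$volume))) {
    sv <- s[s$volume == v, ]
    rows[[length(rows) + 1L]] <- insRow("prompt_user", message = sprintf(
      "Place a fresh selective agar tray for the %g ul spots", v))
    for (i in seq_len(nrow(sv)))
      rows[[length(rows) + 1L]] <- insTransfer(
        "transformation_plate", sv$well[i], sv$tray[i], sv$gridWell[i],
        sv$volume[i], fresh)
  }
  planned <- stats::setNames(w$dnaVolume + w$socVolume, w$well)
  trays <- unique(s$tray)
  deck <- c(slot_1 = "assembly_plate", tempdeck = "transformation_plate",
            slot_3 = "reagents")
  deck <- c(deck, stats::setNames(trays, paste0("tray_", seq_along(trays))))
  meta <- list(step = "transformation",
               plannedWellVolumes = as.list(planned),
               spotGrid = list(rows = 8L, cols = 12L,
                               pitchMm = p$gridPitchMm,
                               axesMirror = "transformation plate"),
               controls = w$well[w$role != "construct"],
               provenance = provenance)
  new("Script", stepId = 4L, deckLayout = deck,
      instructions = bindIns(rows), metadata = meta)
})

#' Summed dispensed volume per destination well of a script
#'
#' Sums the volume of every `transfer` instruction by destination; used to
#' check ledger equality against a plan's volume table. `aspirate`
#' removals are not counted.
#'
#' @param script a [Script-class].
#' @param labware restrict to one destination labware label (optional).
#' @return data.frame with `destLabware`, `destWell`, `volume`.
#' @export
volumeLedger <- function(script, labware = NULL) {
  ins <- instructions(script)
  tr <- ins[ins$verb == "transfer", ]
  if (!is.null(labware)) tr <- tr[tr$destLabware %in% labware, ]
  if (nrow(tr) == 0L)
    return(data.frame(destLabware = character(), destWell = character(),
                      volume = numeric(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(volume ~ destLabware + destWell, data = tr, FUN = sum)
  agg[order(agg$destLabware, wellOrderKey(agg$destWell)), , drop = FALSE]
}

wellOrderKey <- function(w) {
  ok <- vapply(w, is_well, TRUE)
  k <- rep(NA_integer_, length(w))
  k[ok] <- wellIndex(w[ok])
  ifelse(is.na(k), 1000L + order(w), k)
}

#' Render a script as a flat picklist
#'
#' One row per liquid movement (`transfer` and `aspirate` instructions):
#' source labware/well, destination labware/well, volume. The JSON
#' rendering carries every instruction, including device verbs and their
#' parameters, and validates against [picklistSchema()].
#'
#' @param script a [Script-class].
#' @param csvFile,jsonFile optional output paths.
#' @return list with `csv` (character lines) and `json` (text), invisibly
#'   written to the given paths.
#' @export
renderPicklist <- function(script, csvFile = NULL, jsonFile = NULL) {
  ins <- instructions(script)
  mv <- ins[ins$verb %in% c("transfer", "aspirate", "dispense"), ]
  header <- "source_labware,source_well,dest_labware,dest_well,volume_ul"
  csv <- c(header, if (nrow(mv)) sprintf("%s,%s,%s,%s,%g",
    mv$sourceLabware, mv$sourceWell, mv$destLabware, mv$destWell, mv$volume))
  jsonObj <- list(
    step = stepId(script),
    deck = as.list(deckLayout(script)),
    instructions = ins)
  json <- jsonlite::toJSON(jsonObj, auto_unbox = TRUE, na = "null",
                           dataframe = "rows", pretty = TRUE)
  if (!is.null(csvFile)) writeLines(csv, csvFile)
  if (!is.null(jsonFile)) writeLines(json, jsonFile)
  invisible(list(csv = csv, json = json))
}

#' JSON schema for the picklist rendering
#' @return the schema as a nested list (serialise with
#'   [jsonlite::toJSON()]).
#' @export
picklistSchema <- function() {
  list(
    `$schema` = "http://json-schema.org/draft-07/schema#",
    title = "basicbuild instruction picklist",
    type = "object",
    required = c("step", "deck", "instructions"),
    properties = list(
      step = list(type = "integer", minimum = 1, maximum = 4),
      deck = list(type = "object"),
      instructions = list(type = "array", items = list(
        type = "object",
        required = c("verb"),
        properties = list(
          verb = list(type = "string",
                      enum = c(TRANSFER_VERBS, DEVICE_VERBS)),
          sourceLabware = list(type = c("string", "null")),
          sourceWell = list(type = c("string", "null")),
          destLabware = list(type = c("string", "null")),
          destWell = list(type = c("string", "null")),
          volume = list(type = c("number", "null"), exclusiveMinimum = 0),
          tipPolicy = list(type = c("string", "null"),
                           enum = c("fresh_tip", "reuse_tip", NA)),
          temperature = list(type = c("number", "null")),
          seconds = list(type = c("number", "null")),
          mixReps = list(type = c("number", "null")),
          message = list(type = c("string", "null"))))))
  )
}

#' Render a script as a human-readable markdown protocol
#'
#' Lists the deck setup, the Step-1 master-mix recipe when present, and
#' the numbered actions; the action list enumerates exactly the liquid
#' movements the picklist carries plus device actions and prompts.
#'
#' @param script a [Script-class].
#' @param file optional output path.
#' @return character vector of markdown lines.
#' @export
renderProtocolText <- function(script, file = NULL) {
  ins <- instructions(script)
  meta <- scriptMetadata(script)
  out <- c(sprintf("# Step %d protocol (%s)", stepId(script),
                   meta$step %||% ""), "",
           "## Deck setup", "")
  dl <- deckLayout(script)
  out <- c(out, sprintf("- %s: %s", names(dl), dl), "")
  if (!is.null(meta$masterMix)) {
    mm <- meta$masterMix
    out <- c(out, "## Clip reaction master mix (prepare manually)", "",
             "| component | per reaction (ul) | total (ul) |",
             "|---|---|---|",
             sprintf("| %s | %g | %g |", names(mm$perReaction),
                     unlist(mm$perReaction), unlist(mm$totals)),
             sprintf("| total | %g | %g |",
                     sum(unlist(mm$perReaction)), sum(unlist(mm$totals))),
             "",
             sprintf("Reactions: %d; excess fraction: %g", mm$nReactions,
                     mm$excessFraction), "")
  }
  out <- c(out, "## Actions", "")
  step <- 0L
  for (i in seq_len(nrow(ins))) {
    r <- ins[i, ]
    txt <- switch(r$verb,
      transfer = sprintf("Transfer %g ul from %s %s to %s %s (%s)",
                         r$volume, r$sourceLabware, r$sourceWell,
                         r$destLabware, r$destWell, r$tipPolicy),
      aspirate = sprintf("Remove %g ul from %s %s to %s (%s)",
                         r$volume, r$sourceLabware, r$sourceWell,
                         r$destLabware, r$tipPolicy),
      mix = sprintf("Mix %s %s (%g repetitions)", r$destLabware,
                    r$destWell, r$mixReps),
      engage_magnet = sprintf("Engage magnet under %s", r$destLabware),
      disengage_magnet = sprintf("Disengage magnet under %s", r$destLabware),
      delay = sprintf("Wait %g s (%s)", r$seconds, r$message),
      set_temperature = sprintf("Set %s temperature to %g C",
                                r$destLabware, r$temperature),
      prompt_user = sprintf("MANUAL: %s", r$message),
      comment = sprintf("(%s)", r$message))
    if (r$verb == "comment") {
      out <- c(out, paste0("*", r$message, "*"), "")
    } else {
      step <- step + 1L
      out <- c(out, sprintf("%d. %s", step, txt))
    }
  }
  if (!is.null(file)) writeLines(out, file)
  out
}

#' Render a script as robot-API-style text
#'
#' A best-effort textual backend generated from the same instruction
#' stream (python-flavoured pseudo-API); it is never executed by this
#' package. Symbolic deck labels are bound to numeric slots in order.
#'
#' @param script a [Script-class].
#' @param file optional output path.
#' @return character vector of script lines.
#' @export
renderRobotScript <- function(script, file = NULL) {
  ins <- instructions(script)
  dl <- deckLayout(script)
  out <- c("# generated robot script (textual backend; do not execute unreviewed)",
           sprintf("# step %d", stepId(script)),
           "from robot_api import protocol", "",
           "def run(ctx):")
  for (i in seq_along(dl))
    out <- c(out, sprintf("    %s = ctx.load_labware('%s', slot=%d)",
                          gsub("[^a-zA-Z0-9_]", "_", dl[i]), dl[i], i))
  if (nrow(ins) == 0L) out <- c(out, "    pass")
  for (i in seq_len(nrow(ins))) {
    r <- ins[i, ]
    line <- switch(r$verb,
      transfer = sprintf("    ctx.transfer(%g, %s['%s'], %s['%s'], new_tip='%s')",
        r$volume, r$sourceLabware, r$sourceWell, r$destLabware, r$destWell,
        if (identical(r$tipPolicy, "fresh_tip")) "always" else "never"),
      aspirate = sprintf("    ctx.transfer(%g, %s['%s'], waste, new_tip='always')",
        r$volume, r$sourceLabware, r$sourceWell),
      mix = sprintf("    ctx.mix(%g, %s['%s'])", r$mixReps, r$destLabware,
                    r$destWell),
      engage_magnet = "    ctx.magdeck.engage()",
      disengage_magnet = "    ctx.magdeck.disengage()",
      delay = sprintf("    ctx.delay(seconds=%g)  # %s", r$seconds, r$message),
      set_temperature = sprintf("    ctx.tempdeck.set_temperature(%g)",
                                r$temperature),
      prompt_user = sprintf("    ctx.pause('%s')", gsub("'", "", r$message)),
      comment = sprintf("    # %s", r$message))
    out <- c(out, line)
  }
  if (!is.null(file)) writeLines(out, file)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
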