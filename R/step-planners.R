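#' Plan SPRI-bead purification of clip reactions (Step 2)
#'
#' Raw clips in the left half of the plate (columns 1-6) are purified on
#' the magnetic module and their eluates deposited in the mirror well of
#' the right half: same row, column + 6 (A1 -> A7, ..., H6 -> H12). Per
#' well: add 54 ul beads, bind, engage magnet, remove supernatant, wash
#' with 150 ul 70\% ethanol (twice by default), dry, resuspend in water,
#' and transfer 38 ul of elutant to the destination well.
#'
#' @param clipPlan a [ClipPlan-class] with wells assigned.
#' @param config configuration list; `config$purification` holds volumes,
#'   wash count and timings.
#' @return a [PurificationPlan-class].
#' @export
planPurification <- function(clipPlan, config = basicConfig()) {
  wells <- clipPlan@wells
  if (nrow(clips(clipPlan)) > 0L && !length(wells))
    stop("assign clip wells before planning purification")
  if (length(wells) && any(wellColumn(wells) > 6L))
    stop("layout error: clip well(s) outside columns 1-6: ",
         paste(wells[wellColumn(wells) > 6L], collapse = ", "))
  mapping <- data.frame(
    sourceWell = wells,
    destWell = if (length(wells))
      paste0(wellRow(wells), wellColumn(wells) + 6L) else character(),
    stringsAsFactors = FALSE)
  new("PurificationPlan", mapping = mapping, params = config$purification)
}

#' Plan annealing assembly of purified clips (Step 3)
#'
#' Each construct receives 1.5 ul from the purified well of every one of
#' its clips plus annealing buffer to a 15 ul total, in its destination
#' well on the assembly plate. With the default volumes a construct may
#' use at most 9 clips, so at least one clip volume of buffer remains.
#'
#' @param designs list of [ConstructDesign-class].
#' @param clipPlan a [ClipPlan-class] with wells assigned.
#' @param purificationPlan the matching [PurificationPlan-class].
#' @param config configuration list; `config$assembly` holds volumes.
#' @return an [AssemblyPlan-class].
#' @export
planAssembly <- function(designs, clipPlan, purificationPlan,
                         config = basicConfig()) {
  ca <- config$assembly
  refs <- constructClips(clipPlan)
  m <- planMapping(purificationPlan)
  purified <- stats::setNames(m$destWell, m$sourceWell)
  maxClips <- floor((ca$totalVolume - ca$clipVolume) / ca$clipVolume)
  rows <- list()
  for (d in designs) {
    idx <- refs[[designName(d)]]
    if (is.null(idx))
      stop("construct '", designName(d), "' is not in the clip plan")
    if (length(idx) > maxClips)
      stop("volume error: construct '", designName(d), "' uses ",
           length(idx), " clips; at most ", maxClips, " fit a ",
           ca$totalVolume, " ul assembly with ", ca$clipVolume,
           " ul each and non-zero buffer")
    src <- unname(purified[clipPlan@wells[idx]])
    if (anyNA(src))
      stop("purification plan does not cover all clips of construct '",
           designName(d), "'")
    buffer <- ca$totalVolume - ca$clipVolume * length(idx)
    rows[[length(rows) + 1L]] <- data.frame(
      construct = designName(d), destWell = destinationWell(d),
      source = c(rep("purified_clip", length(idx)), "annealing_buffer"),
      sourceWell = c(src, NA_character_),
      volume = c(rep(ca$clipVolume, length(idx)), buffer),
      stringsAsFactors = FALSE)
  }
  transfers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(construct = character(), destWell = character(),
               source = character(), sourceWell = character(),
               volume = numeric(), stringsAsFactors = FALSE)
  new("AssemblyPlan", transfers = transfers,
      totalVolume = ca$totalVolume, clipVolume = ca$clipVolume)
}

#' Plan transformation and agar spotting (Step 4)
#'
#' Each assembly is mixed with competent cells at 4 C (5 ul assembly into
#' 20 ul cells in the construct's well of the cell plate), heat-shocked
#' (user prompt; external thermocycler, per the cell manufacturer's
#' instructions), recovered in 125 ul SOC for 1 h at 37 C, then spotted
#' onto one single-well agar tray per requested spot volume (5 and/or
#' 10 ul). The spot grid is 8 x 12 at 9 mm pitch and mirrors the
#' transformation plate, so grid coordinate == plate well. With controls
#' enabled, wells A12-H12 are reserved for backbone-plasmid (A12-D12) and
#' no-plasmid (E12-H12) controls, leaving at most 88 construct wells.
#'
#' @param designs list of [ConstructDesign-class].
#' @param assemblyPlan an [AssemblyPlan-class].
#' @param config configuration list; `config$transformation` holds
#'   volumes, `spotVolumes` and `controlsEnabled`.
#' @return a [TransformationPlan-class].
#' @export
planTransformation <- function(designs, assemblyPlan, config = basicConfig()) {
  ct <- config$transformation
  if (!all(ct$spotVolumes %in% c(5, 10)))
    stop("spot volumes must be drawn from {5, 10} ul")
  controls <- if (isTRUE(ct$controlsEnabled)) paste0(LETTERS[1:8], 12L)
              else character()
  conWells <- vapply(designs, destinationWell, "")
  if (length(controls)) {
    if (length(designs) > 88L)
      stop(capacityError(sprintf(
        "capacity exceeded: %d constructs but controls reserve wells A12-H12 (max 88)",
        length(designs))))
    clash <- intersect(conWells, controls)
    if (length(clash))
      stop("construct well(s) collide with reserved control wells: ",
           paste(clash, collapse = ", "))
  }
  wells <- data.frame(
    label = c(vapply(designs, designName, ""),
              if (length(controls)) c(paste0("backbone_control_", 1:4),
                                      paste0("no_plasmid_control_", 1:4))),
    well = c(conWells, controls),
    role = c(rep("construct", length(designs)),
             rep(c("backbone_control", "no_plasmid_control"),
                 each = if (length(controls)) 4L else 0L)),
    assemblyWell = c(conWells, rep(NA_character_, length(controls))),
    stringsAsFactors = FALSE)
  wells$assemblyWell[wells$role == "no_plasmid_control"] <- NA_character_
  wells$dnaVolume <- ifelse(wells$role == "no_plasmid_control", 0, ct$dnaVolume)
  wells$cellVolume <- ct$cellVolume
  wells$socVolume <- ct$socVolume

  spots <- do.call(rbind, lapply(ct$spotVolumes, function(v) {
    data.frame(label = wells$label, well = wells$well,
               tray = sprintf("agar_tray_%gul", v),
               gridWell = wells$well, volume = v, stringsAsFactors = FALSE)
  }))
  if (is.null(spots))
    spots <- data.frame(label = character(), well = character(),
                        tray = character(), gridWell = character(),
                        volume = numeric(), stringsAsFactors = FALSE)
  new("TransformationPlan", wells = wells, spots = spots,
      params = ct[c("spotVolumes", "controlsEnabled", "heatShock",
                    "recoverySeconds", "recoveryTemperature",
                    "setupTemperature", "gridPitchMm")])
}
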