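#' Default run configuration
#'
#' All tunable volumes, capacities, timings and policies in one nested list.
#' Values are microlitres unless noted. A YAML file with the same structure
#' can override any subset (see `file`); unknown keys are rejected.
#'
#' Key defaults:
#' \describe{
#'   \item{clip}{`totalVolume` 30, `masterMixVolume` 20, `partVolume` 1,
#'     `linkerHalfVolume` 1 (per half), master-mix recipe 3 ul 10x ligase
#'     buffer + 1 ul BsaI + 0.5 ul T4 ligase + water to 20 ul per reaction,
#'     `excessFraction` 0.1 for manual-mix dead volume.}
#'   \item{capacity}{48 clip reactions (left half-plate), 96 constructs.}
#'   \item{purification}{54 ul SPRI beads, 2 washes of 150 ul 70\% ethanol,
#'     resuspension in 40 ul water, 38 ul elutant transferred; bind 300 s,
#'     settle 60 s, dry 300 s.}
#'   \item{assembly}{15 ul total, 1.5 ul per purified clip, annealing
#'     buffer (20 mM Tris-HCl pH 8.0, 10 mM MgCl2, 50 mM KCl) to volume.}
#'   \item{transformation}{20 ul competent cells, 5 ul assembly aliquot,
#'     125 ul SOC, 1 h recovery at 37 C after heat shock (prompted, per the
#'     cell manufacturer's instructions); spot volumes 5 and 10 ul on one
#'     agar tray each (8 x 12 grid, 9 mm pitch); controls in A12-H12.}
#' }
#'
#' @param file optional YAML file of overrides.
#' @param overrides optional named list of overrides (applied after `file`).
#' @return nested configuration list.
#' @examples
#' cfg <- basicConfig()
#' cfg$assembly$totalVolume
#' @export
basicConfig <- function(file = NULL, overrides = NULL) {
  cfg <- list(
    clip = list(
      totalVolume = 30,
      masterMixVolume = 20,
      partVolume = 1,
      linkerHalfVolume = 1,
      masterMix = c(ligase_buffer_10x = 3, bsaI = 1, t4_ligase = 0.5,
                    water = 15.5),
      excessFraction = 0.1,
      thermocycle = paste("20 cycles (37 C 2 min, 20 C 1 min),",
                          "then 60 C 5 min; external thermocycler")
    ),
    capacity = list(maxClips = 48L, maxConstructs = 96L),
    purification = list(
      beadVolume = 54, ethanolVolume = 150, nWashes = 2L,
      elutionVolume = 40, elutantVolume = 38,
      bindSeconds = 300L, settleSeconds = 60L, drySeconds = 300L
    ),
    assembly = list(
      totalVolume = 15, clipVolume = 1.5,
      buffer = "20 mM Tris-HCl pH 8.0, 10 mM MgCl2, 50 mM KCl",
      anneal = "50 C for 45 min; external thermocycler"
    ),
    transformation = list(
      cellVolume = 20, dnaVolume = 5, socVolume = 125,
      heatShock = "heat shock per the competent-cell manufacturer's instructions (e.g. 42 C, 30 s)",
      recoverySeconds = 3600L, recoveryTemperature = 37,
      setupTemperature = 4,
      spotVolumes = c(5, 10),
      controlsEnabled = TRUE,
      gridPitchMm = 9
    ),
    tips = list(dnaPolicy = "fresh_tip", reagentPolicy = "reuse_tip"),
    deck = list(
      clip_plate = "96-well PCR plate on magnetic module",
      part_plate = "96-well source plate (parts, 200 ng/ul)",
      linker_plate = "96-well source plate (half-linkers)",
      reagents = "reagent reservoir (water, master mix, beads, ethanol, buffer, SOC)",
      transformation_plate = "96-well competent-cell plate on temperature module",
      agar_tray = "single-well agar tray per spot volume"
    )
  )
  if (!is.null(file)) {
    cfg <- mergeConfig(cfg, yaml::read_yaml(file), "config file")
  }
  if (!is.null(overrides)) {
    cfg <- mergeConfig(cfg, overrides, "overrides")
  }
  cfg
}

mergeConfig <- function(base, over, what) {
  if (!is.list(over)) stop("configuration ", what, " must be a named list")
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown configuration key(s) in ", what, ": ",
         paste(unknown, collapse = ", "))
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
      mergeConfig(base[[k]], over[[k]], what)
    } else {
      over[[k]]
    }
  }
  base
}
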