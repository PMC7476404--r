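#' Derive the unique clip reactions implied by a design set
#'
#' Walking each design's circular alternation yields one clip per part:
#' the triple (linker before the part, part, linker after the part); the
#' linker "after" the last part wraps to the design's first linker. Clips
#' are deduplicated across all designs by the full triple; the order of
#' first occurrence (scanning designs in input order) is preserved, so the
#' same inputs always produce the same clip table.
#'
#' @param designs list of [ConstructDesign-class] (validated).
#' @return a [ClipPlan-class] with `clips` and `constructRefs` filled;
#'   wells and volumes are assigned by [assignClipWells()] and
#'   [computeClipVolumes()].
#' @examples
#' d <- constructDesign("toy", "A1", c("LMS", "backbone", "LMP", "insert"))
#' clips(deriveClips(list(d)))
#' @export
deriveClips <- function(designs) {
  seen <- character()
  rows <- list()
  refs <- list()
  for (d in designs) {
    el <- designElements(d)
    n <- length(el)
    idx <- integer(n %/% 2L)
    for (k in seq_len(n %/% 2L)) {
      pPos <- 2L * k
      prefix <- el[pPos - 1L]
      part <- el[pPos]
      suffix <- if (pPos + 1L <= n) el[pPos + 1L] else el[1L]
      key <- paste(prefix, part, suffix, sep = "\r")
      hit <- match(key, seen)
      if (is.na(hit)) {
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- data.frame(
          prefix = prefix, part = part, suffix = suffix,
          stringsAsFactors = FALSE)
        hit <- length(seen)
      }
      idx[k] <- hit
    }
    refs[[designName(d)]] <- idx
  }
  clips <- if (length(rows)) do.call(rbind, rows) else
    data.frame(prefix = character(), part = character(),
               suffix = character(), stringsAsFactors = FALSE)
  new("ClipPlan", clips = clips, wells = character(),
      constructRefs = refs, volumes = clips[0, 0])
}

#' Enforce the platform capacities
#'
#' One run supports at most 48 clip reactions (the left half of the clip
#' plate) and at most 96 constructs (one assembly plate).
#'
#' @param plan a [ClipPlan-class].
#' @param nConstructs number of constructs in the run (defaults to the
#'   plan's construct count).
#' @param config configuration list, see [basicConfig()].
#' @return `invisible(TRUE)` when within capacity; otherwise an error of
#'   class `capacityError` stating the overage.
#' @export
checkCapacity <- function(plan, nConstructs = length(constructClips(plan)),
                          config = basicConfig()) {
  nClips <- nrow(clips(plan))
  maxClips <- config$capacity$maxClips
  maxCon <- config$capacity$maxConstructs
  if (nClips > maxClips)
    stop(capacityError(sprintf(
      "capacity exceeded: %d unique clip reactions required but at most %d fit the left half-plate (%d over)",
      nClips, maxClips, nClips - maxClips)))
  if (nConstructs > maxCon)
    stop(capacityError(sprintf(
      "capacity exceeded: %d constructs requested but at most %d fit one plate (%d over)",
      nConstructs, maxCon, nConstructs - maxCon)))
  invisible(TRUE)
}

capacityError <- function(msg) {
  structure(class = c("capacityError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Assign clip-reaction wells
#'
#' Clips are placed column-major (A1, B1, ..., H1, A2, ...) into the left
#' half of the clip plate, columns 1-6, without gaps; purification later
#' mirrors each clip into the right half.
#'
#' @param plan a [ClipPlan-class] from [deriveClips()].
#' @param config configuration list.
#' @return the plan with `clipWells()` filled.
#' @export
assignClipWells <- function(plan, config = basicConfig()) {
  checkCapacity(plan, config = config)
  n <- nrow(clips(plan))
  plan@wells <- if (n) indexToWell(seq_len(n)) else character()
  validObject(plan)
  plan
}

#' Per-clip reagent volumes
#'
#' Each 30 ul clip reaction receives 20 ul master mix, the part, one
#' prefix half-linker, one suffix half-linker, and water to volume. Parts
#' are assumed pre-diluted to working concentration (200 ng/ul), so
#' volumes are fixed per reagent class rather than normalised by
#' concentration.
#'
#' @param plan a [ClipPlan-class]; pass a plan with wells assigned to get
#'   the per-well volume table.
#' @param config configuration list; `config$clip` supplies
#'   `totalVolume`, `masterMixVolume`, `partVolume`, `linkerHalfVolume`.
#' @return the plan with `clipVolumes()` filled: one row per clip with
#'   columns `master_mix`, `part`, `prefix_half`, `suffix_half`, `water`
#'   summing to the total volume.
#' @export
computeClipVolumes <- function(plan, config = basicConfig()) {
  cc <- config$clip
  water <- cc$totalVolume - cc$masterMixVolume - cc$partVolume -
    2 * cc$linkerHalfVolume
  if (water < 0)
    stop("configuration error: negative water volume (", water,
         " ul); reduce part/linker volumes or raise the total")
  n <- nrow(clips(plan))
  plan@volumes <- data.frame(
    master_mix = rep(cc$masterMixVolume, n),
    part = rep(cc$partVolume, n),
    prefix_half = rep(cc$linkerHalfVolume, n),
    suffix_half = rep(cc$linkerHalfVolume, n),
    water = rep(water, n))
  plan
}

#' Master-mix recipe for n clip reactions
#'
#' Per 20 ul reaction: 3 ul 10x T4 ligase buffer, 1 ul BsaI-HFv2, 0.5 ul
#' T4 DNA ligase, 15.5 ul water. The mix is prepared manually; totals are
#' scaled by `1 + excessFraction` for dead volume and emitted in the
#' Step-1 meta-information, never dispensed by the planner.
#'
#' @param nClips number of clip reactions (>= 1).
#' @param excessFraction dimensionless excess, >= 0.
#' @param config configuration list.
#' @return a [MasterMixRecipe-class].
#' @examples
#' masterMixRecipe(38, excessFraction = 0)
#' @export
masterMixRecipe <- function(nClips,
                            excessFraction = basicConfig()$clip$excessFraction,
                            config = basicConfig()) {
  nClips <- as.integer(nClips)
  if (is.na(nClips) || nClips < 1L)
    stop("nothing to mix: master mix requires at least one clip reaction")
  per <- config$clip$masterMix
  new("MasterMixRecipe", perReaction = per, nReactions = nClips,
      excessFraction = excessFraction,
      totals = per * nClips * (1 + excessFraction))
}
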