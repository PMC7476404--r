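## Accessor generics and show() methods. Slots are never touched directly by
## user code; everything goes through these.

#' @rdname ConstructDesign-class
#' @param object,x a package object.
#' @export
setGeneric("designName", function(x) standardGeneric("designName"))
#' @rdname ConstructDesign-class
#' @export
setGeneric("destinationWell", function(x) standardGeneric("destinationWell"))
#' @rdname ConstructDesign-class
#' @export
setGeneric("designElements", function(x) standardGeneric("designElements"))
#' @rdname ConstructDesign-class
#' @export
setGeneric("designLinkers", function(x) standardGeneric("designLinkers"))
#' @rdname ConstructDesign-class
#' @export
setGeneric("designParts", function(x) standardGeneric("designParts"))

#' @rdname ConstructDesign-class
#' @export
setMethod("designName", "ConstructDesign", function(x) x@name)
#' @rdname ConstructDesign-class
#' @export
setMethod("destinationWell", "ConstructDesign", function(x) x@well)
#' @rdname ConstructDesign-class
#' @export
setMethod("designElements", "ConstructDesign", function(x) x@elements)
#' @rdname ConstructDesign-class
#' @export
setMethod("designLinkers", "ConstructDesign",
  function(x) x@elements[seq(1L, length(x@elements), by = 2L)])
#' @rdname ConstructDesign-class
#' @export
setMethod("designParts", "ConstructDesign",
  function(x) x@elements[seq(2L, length(x@elements), by = 2L)])

setMethod("show", "ConstructDesign", function(object) {
  cat("ConstructDesign '", object@name, "' -> ", object@well, "\n", sep = "")
  cat("  ", paste(object@elements, collapse = " | "), "\n", sep = "")
})

#' @rdname PlateMap-class
#' @param x,object a [PlateMap-class].
#' @export
setGeneric("plateId", function(x) standardGeneric("plateId"))
#' @rdname PlateMap-class
#' @export
setGeneric("plateEntries", function(x) standardGeneric("plateEntries"))
#' @rdname PlateMap-class
#' @param name reagent name(s) to look up.
#' @export
setGeneric("reagentWell", function(x, name) standardGeneric("reagentWell"))

#' @rdname PlateMap-class
#' @export
setMethod("plateId", "PlateMap", function(x) x@plateId)
#' @rdname PlateMap-class
#' @export
setMethod("plateEntries", "PlateMap", function(x) x@entries)
#' @rdname PlateMap-class
#' @export
setMethod("reagentWell", "PlateMap", function(x, name) {
  w <- x@entries[name]
  if (anyNA(w))
    stop("unknown reagent(s) on plate '", x@plateId, "': ",
         paste(name[is.na(w)], collapse = ", "))
  unname(w)
})

setMethod("show", "PlateMap", function(object) {
  cat("PlateMap '", object@plateId, "' (", object@kind, "): ",
      length(object@entries), " reagents\n", sep = "")
})

#' @rdname ClipPlan-class
#' @param x,object a [ClipPlan-class].
#' @export
setGeneric("clips", function(x) standardGeneric("clips"))
#' @rdname ClipPlan-class
#' @export
setGeneric("clipWells", function(x) standardGeneric("clipWells"))
#' @rdname ClipPlan-class
#' @export
setGeneric("constructClips", function(x) standardGeneric("constructClips"))
#' @rdname ClipPlan-class
#' @export
setGeneric("clipVolumes", function(x) standardGeneric("clipVolumes"))

#' @rdname ClipPlan-class
#' @export
setMethod("clips", "ClipPlan", function(x) x@clips)
#' @rdname ClipPlan-class
#' @export
setMethod("clipWells", "ClipPlan", function(x) {
  w <- x@wells
  if (length(w)) names(w) <- clipKeys(x@clips)
  w
})
#' @rdname ClipPlan-class
#' @export
setMethod("constructClips", "ClipPlan", function(x) x@constructRefs)
#' @rdname ClipPlan-class
#' @export
setMethod("clipVolumes", "ClipPlan", function(x) x@volumes)

setMethod("show", "ClipPlan", function(object) {
  cat("ClipPlan:", nrow(object@clips), "unique clips for",
      length(object@constructRefs), "constructs\n")
  if (length(object@wells))
    cat("  wells assigned:", object@wells[1], "...",
        object@wells[length(object@wells)], "\n")
})

setMethod("show", "MasterMixRecipe", function(object) {
  cat("MasterMixRecipe for ", object@nReactions, " reactions (excess ",
      object@excessFraction * 100, "%):\n", sep = "")
  tab <- data.frame(per_reaction_ul = object@perReaction,
                    total_ul = object@totals)
  print(tab)
})

#' @rdname PurificationPlan-class
#' @param x,object a plan object.
#' @export
setGeneric("planMapping", function(x) standardGeneric("planMapping"))
#' @rdname PurificationPlan-class
#' @export
setGeneric("planParams", function(x) standardGeneric("planParams"))

#' @rdname PurificationPlan-class
#' @export
setMethod("planMapping", "PurificationPlan", function(x) x@mapping)
#' @rdname PurificationPlan-class
#' @export
setMethod("planParams", "PurificationPlan", function(x) x@params)

setMethod("show", "PurificationPlan", function(object) {
  cat("PurificationPlan:", nrow(object@mapping), "clip wells;",
      object@params$beadVolume, "ul beads,",
      object@params$nWashes, "x", object@params$ethanolVolume, "ul ethanol,",
      object@params$elutantVolume, "ul elutant out\n")
})

#' @rdname AssemblyPlan-class
#' @param x,object an [AssemblyPlan-class].
#' @export
setGeneric("assemblyTransfers", function(x) standardGeneric("assemblyTransfers"))
#' @rdname AssemblyPlan-class
#' @export
setMethod("assemblyTransfers", "AssemblyPlan", function(x) x@transfers)

setMethod("show", "AssemblyPlan", function(object) {
  cat("AssemblyPlan:", length(unique(object@transfers$construct)),
      "constructs at", object@totalVolume, "ul each\n")
})

#' @rdname TransformationPlan-class
#' @param x,object a [TransformationPlan-class].
#' @export
setGeneric("transformationWells", function(x) standardGeneric("transformationWells"))
#' @rdname TransformationPlan-class
#' @export
setGeneric("spotPlan", function(x) standardGeneric("spotPlan"))

#' @rdname TransformationPlan-class
#' @export
setMethod("transformationWells", "TransformationPlan", function(x) x@wells)
#' @rdname TransformationPlan-class
#' @export
setMethod("spotPlan", "TransformationPlan", function(x) x@spots)
#' @rdname TransformationPlan-class
#' @export
setMethod("planParams", "TransformationPlan", function(x) x@params)

setMethod("show", "TransformationPlan", function(object) {
  cat("TransformationPlan:", nrow(object@wells), "transformations,",
      nrow(object@spots), "spots\n")
})

#' @rdname Script-class
#' @param x,object a [Script-class].
#' @export
setGeneric("stepId", function(x) standardGeneric("stepId"))
#' @rdname Script-class
#' @export
setGeneric("deckLayout", function(x) standardGeneric("deckLayout"))
#' @rdname Script-class
#' @export
setGeneric("instructions", function(x) standardGeneric("instructions"))
#' @rdname Script-class
#' @export
setGeneric("scriptMetadata", function(x) standardGeneric("scriptMetadata"))

#' @rdname Script-class
#' @export
setMethod("stepId", "Script", function(x) x@stepId)
#' @rdname Script-class
#' @export
setMethod("deckLayout", "Script", function(x) x@deckLayout)
#' @rdname Script-class
#' @export
setMethod("instructions", "Script", function(x) x@instructions)
#' @rdname Script-class
#' @export
setMethod("scriptMetadata", "Script", function(x) x@metadata)

setMethod("show", "Script", function(object) {
  tr <- sum(object@instructions$verb %in% TRANSFER_VERBS)
  cat("Script step ", object@stepId, ": ", nrow(object@instructions),
      " instructions (", tr, " transfers), deck: ",
      paste(object@deckLayout, collapse = ", "), "\n", sep = "")
})

#' @rdname DnaFragment-class
#' @param x,object a [DnaFragment-class].
#' @export
setGeneric("fragmentSeq", function(x) standardGeneric("fragmentSeq"))
#' @rdname DnaFragment-class
#' @export
setGeneric("leftOverhang", function(x) standardGeneric("leftOverhang"))
#' @rdname DnaFragment-class
#' @export
setGeneric("rightOverhang", function(x) standardGeneric("rightOverhang"))

#' @rdname DnaFragment-class
#' @export
setMethod("fragmentSeq", "DnaFragment", function(x) x@seq)
#' @rdname DnaFragment-class
#' @export
setMethod("leftOverhang", "DnaFragment",
  function(x) substr(x@seq, 1L, x@lOvh))
#' @rdname DnaFragment-class
#' @export
setMethod("rightOverhang", "DnaFragment",
  function(x) substring(x@seq, nchar(x@seq) - x@rOvh + 1L))

setMethod("show", "DnaFragment", function(object) {
  cat("DnaFragment: ", nchar(object@seq), " nt, overhangs ",
      object@lOvh, "/", object@rOvh, "\n", sep = "")
})

#' @rdname PredictedConstruct-class
#' @param x,object a [PredictedConstruct-class].
#' @export
setGeneric("predictedSeq", function(x) standardGeneric("predictedSeq"))
#' @rdname PredictedConstruct-class
#' @export
setGeneric("constructFeatures", function(x) standardGeneric("constructFeatures"))
#' @rdname PredictedConstruct-class
#' @export
setGeneric("constructNotes", function(x) standardGeneric("constructNotes"))

#' @rdname PredictedConstruct-class
#' @export
setMethod("predictedSeq", "PredictedConstruct", function(x) x@seq)
#' @rdname PredictedConstruct-class
#' @export
setMethod("constructFeatures", "PredictedConstruct", function(x) x@features)
#' @rdname PredictedConstruct-class
#' @export
setMethod("constructNotes", "PredictedConstruct", function(x) x@notes)
#' @rdname PredictedConstruct-class
#' @export
setMethod("designName", "PredictedConstruct", function(x) x@name)

setMethod("show", "PredictedConstruct", function(object) {
  cat("PredictedConstruct '", object@name, "': ", nchar(object@seq),
      " bp circular, ", nrow(object@features), " features\n", sep = "")
})

## internal: stable clip keys for naming
clipKeys <- function(clips) {
  paste(clips$prefix, clips$part, clips$suffix, sep = "|")
}
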