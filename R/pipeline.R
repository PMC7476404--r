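#' Compile a design set into the four step scripts
#'
#' The end-to-end planner: validates the designs against the plates,
#' derives and deduplicates clip reactions, enforces capacities, assigns
#' wells, computes volumes and the master-mix recipe, plans purification,
#' assembly and transformation, and emits the four instruction scripts
#' with shared provenance metadata.
#'
#' @param designs list of [ConstructDesign-class].
#' @param partPlate,linkerPlate source-plate [PlateMap-class] objects.
#' @param config configuration list, see [basicConfig()].
#' @return list of class `BasicRun`: `issues`, `clipPlan`, `recipe`,
#'   `purification`, `assembly`, `transformation`, `scripts` (list of four
#'   [Script-class]), `provenance`.
#' @examples
#' fx <- makeFactorialDesign()
#' run <- planBasicRun(fx$designs, fx$partPlate, fx$linkerPlate)
#' nrow(clips(run$clipPlan))  # 38
#' @export
planBasicRun <- function(designs, partPlate, linkerPlate,
                         config = basicConfig()) {
  plan <- deriveClips(designs)
  checkCapacity(plan, length(designs), config)

  issues <- validateDesigns(designs, partPlate, linkerPlate)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("validation failed with ", nrow(errs), " error(s); first: ",
         errs$message[1L], " [", errs$subject[1L], "]")
  plan <- assignClipWells(plan, config)
  plan <- computeClipVolumes(plan, config)
  recipe <- masterMixRecipe(nrow(clips(plan)), config$clip$excessFraction,
                            config)
  purification <- planPurification(plan, config)
  assembly <- planAssembly(designs, plan, purification, config)
  transformation <- planTransformation(designs, assembly, config)

  provenance <- list(
    package = as.character(utils::packageVersion("basicbuild")),
    nConstructs = length(designs),
    nClips = nrow(clips(plan)),
    inputDigests = list(
      constructs = contentDigest(writeConstructCsv(designs)),
      partPlate = contentDigest(writePlateCsv(partPlate)),
      linkerPlate = contentDigest(writePlateCsv(linkerPlate))),
    configDigest = contentDigest(yaml::as.yaml(config)))

  scripts <- list(
    step1 = emitScript(plan, partPlate, linkerPlate, recipe = recipe,
                       config = config, provenance = provenance),
    step2 = emitScript(purification, config = config, provenance = provenance),
    step3 = emitScript(assembly, config = config, provenance = provenance),
    step4 = emitScript(transformation, config = config,
                       provenance = provenance))

  structure(list(issues = issues, clipPlan = plan, recipe = recipe,
                 purification = purification, assembly = assembly,
                 transformation = transformation, scripts = scripts,
                 provenance = provenance),
            class = "BasicRun")
}

#' @export
print.BasicRun <- function(x, ...) {
  cat("BasicRun:", x$provenance$nConstructs, "constructs,",
      x$provenance$nClips, "clip reactions, 4 scripts\n")
  invisible(x)
}

#' MD5 digest of text content
#' @param lines character vector of lines.
#' @return hex digest string.
#' @keywords internal
contentDigest <- function(lines) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf)
  unname(tools::md5sum(tf))
}

#' Write all run artefacts to a directory
#'
#' For each of the four steps: the picklist (CSV + JSON), the markdown
#' protocol and the robot-script text; plus the issues report (JSON
#' lines), the picklist schema and a run manifest JSON tying everything to
#' the input digests.
#'
#' @param run a `BasicRun` from [planBasicRun()].
#' @param outDir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeRunOutputs <- function(run, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character()
  add <- function(nm, p) paths[nm] <<- p
  for (s in run$scripts) {
    id <- stepId(s)
    base <- file.path(outDir, sprintf("step%d", id))
    renderPicklist(s, csvFile = paste0(base, "_picklist.csv"),
                   jsonFile = paste0(base, "_picklist.json"))
    renderProtocolText(s, file = paste0(base, "_protocol.md"))
    renderRobotScript(s, file = paste0(base, "_robot.py.txt"))
    add(sprintf("step%d_picklist_csv", id), paste0(base, "_picklist.csv"))
    add(sprintf("step%d_picklist_json", id), paste0(base, "_picklist.json"))
    add(sprintf("step%d_protocol", id), paste0(base, "_protocol.md"))
    add(sprintf("step%d_robot", id), paste0(base, "_robot.py.txt"))
  }
  issuesPath <- file.path(outDir, "issues.jsonl")
  writeIssuesJson(run$issues, issuesPath)
  add("issues", issuesPath)
  schemaPath <- file.path(outDir, "picklist_schema.json")
  writeLines(jsonlite::toJSON(picklistSchema(), auto_unbox = TRUE,
                              pretty = TRUE), schemaPath)
  add("schema", schemaPath)
  manifest <- list(
    provenance = run$provenance,
    steps = lapply(run$scripts, function(s) list(
      step = stepId(s),
      instructions = nrow(instructions(s)),
      transfers = sum(instructions(s)$verb %in% TRANSFER_VERBS),
      deck = as.list(deckLayout(s)))),
    masterMix = scriptMetadata(run$scripts$step1)$masterMix,
    files = as.list(basename(paths)))
  manifestPath <- file.path(outDir, "run_manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              na = "null"), manifestPath)
  add("manifest", manifestPath)
  invisible(paths)
}
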