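emitToy <- function() {
  designs <- list(toyDesign("C1", "A1"),
                  toyDesign("C2", "B1",
                            c("LMS", "backbone", "LMP", "geneA", "L1", "geneB")))
  plates <- toyPlates(designs)
  planBasicRun(designs, plates$parts, plates$linkers)
}

test_that("Step-1 script dispenses exactly 30 ul into every clip well", {
  run <- emitToy()
  led <- volumeLedger(run$scripts$step1, "clip_plate")
  expect_true(all(led$volume == 30))
  expect_equal(nrow(led), nrow(clips(run$clipPlan)))
  # planned ledger equality, well by well
  planned <- scriptMetadata(run$scripts$step1)$plannedWellVolumes
  expect_equal(led$volume, unname(unlist(planned[led$destWell])))
})

test_that("scripts realize each planned transfer exactly once", {
  run <- emitToy()
  # step 3: every (source well, dest well, volume) triple in the plan
  # appears exactly once in the instruction stream
  tr <- assemblyTransfers(run$assembly)
  ins <- instructions(run$scripts$step3)
  moved <- ins[ins$verb == "transfer", ]
  planKeys <- sort(paste(ifelse(is.na(tr$sourceWell), "annealing_buffer",
                                tr$sourceWell), tr$destWell, tr$volume))
  insKeys <- sort(paste(ifelse(moved$sourceLabware == "reagents",
                               moved$sourceWell, moved$sourceWell),
                        moved$destWell, moved$volume))
  expect_equal(insKeys, planKeys)
})

test_that("magnet engages before any supernatant removal", {
  run <- emitToy()
  ins <- instructions(run$scripts$step2)
  firstEngage <- which(ins$verb == "engage_magnet")[1L]
  removals <- which(ins$verb == "aspirate")
  expect_true(length(removals) > 0L)
  expect_true(all(removals > firstEngage))
})

test_that("emission is deterministic: same plan, byte-identical renderings", {
  run1 <- emitToy()
  run2 <- emitToy()
  for (k in 1:4) {
    s1 <- run1$scripts[[k]]; s2 <- run2$scripts[[k]]
    expect_identical(instructions(s1), instructions(s2))
    expect_identical(renderPicklist(s1)$csv, renderPicklist(s2)$csv)
    expect_identical(renderPicklist(s1)$json, renderPicklist(s2)$json)
    expect_identical(renderProtocolText(s1), renderProtocolText(s2))
    expect_identical(renderRobotScript(s1), renderRobotScript(s2))
  }
  # provenance digests tie identical inputs to identical scripts
  expect_identical(run1$provenance$inputDigests, run2$provenance$inputDigests)
})

test_that("picklist rows match the plan structure and the protocol text", {
  five <- constructDesign("c5", "A1",
    c("LMS", "bb", "LMP", "prom", "U1", "g1", "U2", "g2", "U3", "g3"))
  plan <- assignClipWells(deriveClips(list(five)))
  pur <- planPurification(plan)
  asm <- planAssembly(list(five), plan, pur)
  s3 <- emitScript(asm)
  pk <- renderPicklist(s3)
  # 5 clips + 1 buffer = 6 transfer rows (plus the header line)
  expect_equal(length(pk$csv) - 1L, 6L)

  # protocol enumerates exactly as many liquid movements as the picklist
  proto <- renderProtocolText(s3)
  nActions <- sum(grepl("^\\d+\\. (Transfer|Remove)", proto))
  expect_equal(nActions, length(pk$csv) - 1L)

  # empty plan -> header-only CSV and a valid minimal robot skeleton
  emptyAsm <- new("AssemblyPlan",
                  transfers = assemblyTransfers(asm)[0, ],
                  totalVolume = 15, clipVolume = 1.5)
  sEmpty <- emitScript(emptyAsm)
  expect_equal(renderPicklist(sEmpty)$csv,
               "source_labware,source_well,dest_labware,dest_well,volume_ul")
  rob <- renderRobotScript(sEmpty)
  expect_true(any(grepl("def run", rob)))
  expect_true(any(grepl("pass|prompt|pause|#", rob)))
})

test_that("Step-1 protocol text carries the master-mix recipe table", {
  run <- emitToy()
  proto <- renderProtocolText(run$scripts$step1)
  expect_true(any(grepl("master mix", proto, ignore.case = TRUE)))
  expect_true(any(grepl("\\| ligase_buffer_10x \\| 3 \\|", proto)))
  expect_true(any(grepl("\\| bsaI \\| 1 \\|", proto)))
  expect_true(any(grepl("\\| t4_ligase \\| 0.5 \\|", proto)))
})

test_that("picklist JSON validates against the published schema", {
  run <- emitToy()
  schema <- picklistSchema()
  verbs <- schema$properties$instructions$items$properties$verb$enum
  for (s in run$scripts) {
    obj <- jsonlite::fromJSON(renderPicklist(s)$json, simplifyDataFrame = TRUE)
    expect_true(all(schema$required %in% names(obj)))
    expect_true(all(obj$instructions$verb %in% verbs))
    tr <- obj$instructions[obj$instructions$verb %in%
                             c("transfer", "aspirate", "dispense"), ]
    expect_true(all(tr$volume > 0))
  }
})

test_that("run outputs land on disk with a manifest", {
  run <- emitToy()
  out <- tempfile("runout")
  paths <- writeRunOutputs(run, out)
  expect_true(all(file.exists(paths)))
  manifest <- jsonlite::fromJSON(file.path(out, "run_manifest.json"))
  expect_equal(manifest$provenance$nConstructs, 2L)
  expect_length(manifest$steps, 4L)
  expect_equal(manifest$masterMix$perReaction$ligase_buffer_10x, 3)
})
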