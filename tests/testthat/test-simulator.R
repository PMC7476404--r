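# toy molecules built by explicit concatenation, so every expected value
# has a string-surgery oracle independent of the fragment machinery

test_that("digestPart releases the planted core with its scar overhangs", {
  set.seed(42)
  toy <- makeToyLibrary(seed = 42, partNames = "ins", linkerNames = c("LMS", "LMP"),
                        designs = FALSE)
  part <- toy$partSeqs$ins
  core <- digestPart(part)
  expect_equal(fragmentSeq(core), oraclePartCore(part))
  expect_equal(leftOverhang(core), toy$scarP)
  expect_equal(rightOverhang(core), toy$scarS)

  # digestion is rotation-invariant for circular molecules
  s <- part@seq
  rot <- partSequence("rot", paste0(substring(s, 51), substr(s, 1, 50)),
                      "circular")
  expect_equal(fragmentSeq(digestPart(rot)), fragmentSeq(core))
})

test_that("methyl protection blocks cutting; extra sites are reported", {
  toy <- makeToyLibrary(seed = 7, partNames = "ins",
                        linkerNames = c("LMS", "LMP"), designs = FALSE)
  part <- toy$partSeqs$ins
  p <- as.integer(regexpr("GGTCTC", part@seq, fixed = TRUE))

  # protect the Prefix site -> only one cuttable site left
  protected <- partSequence("prot", part@seq, "circular", methyl = p + 1L)
  expect_error(digestPart(protected), "missing-site")

  # plant a third site inside the core -> internal-site error
  q <- as.integer(regexpr("GAGACC", part@seq, fixed = TRUE))
  withSite <- paste0(substr(part@seq, 1, p + 30L), "GGTCTC",
                     substring(part@seq, p + 31L))
  expect_error(digestPart(partSequence("x", withSite, "circular")),
               "internal-site")
  # the error names the planted position
  expect_error(digestPart(partSequence("x", withSite, "circular")),
               as.character(p + 31L))

  # monotonicity: methyl marks never increase the number of cuts
  model <- restrictionModel()
  for (seed in 1:10) {
    set.seed(seed)
    seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
    all <- basicbuild:::findRecognitionSites(seq, model, circular = TRUE)
    marks <- sort(sample.int(400, 30))
    marked <- basicbuild:::findRecognitionSites(seq, model, methyl = marks,
                                                circular = TRUE)
    expect_lte(sum(!marked$protected), sum(!all$protected))
    expect_equal(nrow(marked), nrow(all))
  }
})

test_that("ligateClip concatenates on matching scars and rejects mismatches", {
  toy <- makeToyLibrary(seed = 3, partNames = "ins",
                        linkerNames = c("LMS", "LMP", "L1"), designs = FALSE)
  core <- digestPart(toy$partSeqs$ins)
  lmp <- toy$linkerSeqs$LMP
  l1 <- toy$linkerSeqs$L1
  clip <- ligateClip(core, lmp, l1)

  # string-concatenation oracle: halves overlap the core at the 4-nt scars
  expected <- joinByOverlap(list(lmp@prefixSeq, fragmentSeq(core),
                                 l1@suffixSeq), 4L)
  expect_equal(fragmentSeq(clip), expected)
  expect_equal(nchar(leftOverhang(clip)), 21L)
  expect_equal(nchar(rightOverhang(clip)), 21L)

  # melt recovers the same three segments
  melted <- meltClip(clip)
  expect_equal(melted$prefixHalf, lmp@prefixSeq)
  expect_equal(melted$core, fragmentSeq(core))
  expect_equal(melted$suffixHalf, l1@suffixSeq)

  # scar mismatch names both 4-mers
  badCore <- dnaFragment(paste0("TTTT", substring(fragmentSeq(core), 5)),
                         lOvh = 4L, rOvh = 4L, meta = list(name = "bad"))
  err <- tryCatch(ligateClip(badCore, lmp, l1), error = conditionMessage)
  expect_match(err, "ligation-incompatibility")
  expect_match(err, "TTTT")
  expect_match(err, toy$scarP)
})

test_that("annealing recovers assembly order from tails, not input order", {
  toy <- makeToyLibrary(seed = 11)
  d <- toy$designs[[1]]
  el <- designElements(d)
  mkClips <- function() {
    n <- length(el)
    lapply(seq(2L, n, by = 2L), function(pPos) {
      nxt <- if (pPos == n) el[1L] else el[pPos + 1L]
      ligateClip(digestPart(toy$partSeqs[[el[pPos]]]),
                 toy$linkerSeqs[[el[pPos - 1L]]], toy$linkerSeqs[[nxt]])
    })
  }
  clipsL <- mkClips()
  pc <- annealAssembly(clipsL, name = "toy1", rotateToPart = el[2L])

  # concatenation oracle, rotated to the same anchor
  oracle <- oracleConstructText(d, toy)
  anchorCore <- oraclePartCore(toy$partSeqs[[el[2L]]])
  expect_equal(predictedSeq(pc), rotateTo(oracle, anchorCore))

  # shuffling clip input order changes nothing
  for (seed in 1:5) {
    set.seed(seed)
    shuffled <- annealAssembly(sample(clipsL), name = "toy1",
                               rotateToPart = el[2L])
    expect_identical(predictedSeq(shuffled), predictedSeq(pc))
    expect_identical(constructFeatures(shuffled), constructFeatures(pc))
  }

  # dropping a clip breaks the circle
  expect_error(annealAssembly(clipsL[-2L], name = "x"),
               "incomplete-assembly")

  # corrupting one tail base breaks annealing
  broken <- clipsL
  s <- fragmentSeq(broken[[1L]])
  flip <- function(ch) chartr("ACGT", "CATG", ch)
  substrRep <- paste0(flip(substr(s, 1, 1)), substring(s, 2))
  broken[[1L]]@seq <- substrRep
  expect_error(annealAssembly(broken, name = "x"), "incomplete-assembly")
})

test_that("predicted lengths follow the concatenation arithmetic", {
  for (seed in c(5, 17)) {
    toy <- makeToyLibrary(seed = seed)
    res <- predictConstructs(toy$designs, toy$partSeqs, toy$linkerSeqs)
    expect_length(res$errors, 0L)
    for (d in toy$designs) {
      pc <- res$constructs[[designName(d)]]
      cores <- vapply(designParts(d), function(p)
        nchar(oraclePartCore(toy$partSeqs[[p]])), 1L)
      linkers <- vapply(designLinkers(d), function(l)
        nchar(fullLinkerText(toy$linkerSeqs[[l]])), 1L)
      # each of the 2k junctions shares one 4-nt scar
      expected <- sum(cores) + sum(linkers) - 4L * (length(cores) * 2L)
      expect_equal(nchar(predictedSeq(pc)), expected)
      expect_length(constructNotes(pc), 0L)
    }
  }
})

test_that("idempotence: re-digestion returns the payload; neutral linkers fail", {
  toy <- makeToyLibrary(seed = 23)
  d <- toy$designs[[1]]
  res <- predictConstructs(list(d), toy$partSeqs, toy$linkerSeqs)
  pc <- res$constructs[[1]]
  rep <- verifyIdempotence(pc)
  expect_true(rep$pass)
  expect_true(rep$prefixFound && rep$suffixFound)

  # the released payload spans from the LMP scar through the LMS scar:
  # rebuild it with the concatenation oracle over the inter-flank elements
  el <- designElements(d)                    # LMS bb LMP p1 L1 p2
  pieces <- list(oraclePartCore(toy$partSeqs[[el[4L]]]),
                 fullLinkerText(toy$linkerSeqs[[el[5L]]]),
                 oraclePartCore(toy$partSeqs[[el[6L]]]))
  expect_equal(fragmentSeq(rep$payload), joinByOverlap(pieces, 4L))

  # same payload, via the expectedPayload argument
  expect_true(verifyIdempotence(pc, expectedPayload =
                                  joinByOverlap(pieces, 4L))$pass)

  # a construct assembled with neutral (non-recapitulating) flanks fails
  neutral <- makeToyLibrary(seed = 23)
  neutral$linkerSeqs$LMS <- linkerSequence(
    "LMS", neutral$linkerSeqs$L3@prefixSeq,
    neutral$linkerSeqs$L3@suffixSeq, methylated = FALSE)
  # (LMS replaced by a siteless linker body with LMS's role)
  res2 <- predictConstructs(list(d), neutral$partSeqs, neutral$linkerSeqs)
  rep2 <- verifyIdempotence(res2$constructs[[1]])
  expect_false(rep2$pass)
  expect_true(any(grepl("missing-Suffix", rep2$reasons)))

  neutral$linkerSeqs$LMP <- linkerSequence(
    "LMP", neutral$linkerSeqs$L2@prefixSeq,
    neutral$linkerSeqs$L2@suffixSeq, methylated = FALSE)
  res3 <- predictConstructs(list(d), neutral$partSeqs, neutral$linkerSeqs)
  rep3 <- verifyIdempotence(res3$constructs[[1]])
  expect_false(rep3$pass)
  expect_true(any(grepl("missing-Prefix", rep3$reasons)))
})

test_that("two assembly rounds match the one-shot concatenation oracle", {
  toy <- makeToyLibrary(seed = 31)
  d <- toy$designs[[1]]
  res <- predictConstructs(list(d), toy$partSeqs, toy$linkerSeqs)
  payload <- verifyIdempotence(res$constructs[[1]])$payload

  # round 2: treat the assembled construct as a stored part and clip it
  # into a fresh backbone via LMS/LMP
  stored <- partSequence("round1_product",
                         predictedSeq(res$constructs[[1]]), "circular")
  clip1 <- ligateClip(digestPart(stored), toy$linkerSeqs$LMP,
                      toy$linkerSeqs$LMS)
  bbClip <- ligateClip(digestPart(toy$partSeqs$backbone),
                       toy$linkerSeqs$LMS, toy$linkerSeqs$LMP)
  round2 <- annealAssembly(list(clip1, bbClip), name = "round2",
                           rotateToPart = "backbone")

  # oracle: same payload re-framed by LMS/backbone/LMP
  oracle <- joinByOverlap(list(
    oraclePartCore(toy$partSeqs$backbone),
    fullLinkerText(toy$linkerSeqs$LMP),
    fragmentSeq(payload),
    fullLinkerText(toy$linkerSeqs$LMS)), 4L)
  oracle <- substr(oracle, 1L, nchar(oracle) - 4L)  # close the circle
  expect_equal(predictedSeq(round2),
               rotateTo(oracle, oraclePartCore(toy$partSeqs$backbone)))
  expect_true(verifyIdempotence(round2)$pass)
})

test_that("predictConstructs collects per-design failures without aborting", {
  toy <- makeToyLibrary(seed = 13)
  partial <- toy$partSeqs
  partial$promoterA <- NULL  # used by toy1 and toy2, not toy3
  res <- predictConstructs(toy$designs, partial, toy$linkerSeqs)
  expect_named(res$errors, c("toy1", "toy2"))
  expect_match(unname(res$errors[1]), "missing-sequence")
  expect_named(res$constructs, "toy3")

  # GenBank emission for the successes
  outDir <- tempfile("gb")
  res2 <- predictConstructs(toy$designs, toy$partSeqs, toy$linkerSeqs,
                            genbankDir = outDir)
  files <- list.files(outDir, pattern = "\\.gb$")
  expect_setequal(files, paste0(c("toy1", "toy2", "toy3"), ".gb"))
  rec <- readGenbank(file.path(outDir, "toy1.gb"))[["toy1"]]
  expect_true(rec$circular)
  expect_equal(rec$seq, predictedSeq(res2$constructs$toy1))
  expect_true(all(c("part", "linker") %in% rec$features$type))
})

test_that("linker configs round-trip through JSON and YAML", {
  toy <- makeToyLibrary(seed = 2, designs = FALSE)
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    writeLinkerConfig(toy$linkerSeqs, f)
    back <- readLinkerConfig(f)
    expect_setequal(names(back), names(toy$linkerSeqs))
    for (nm in names(back)) {
      expect_equal(back[[nm]]@prefixSeq, toy$linkerSeqs[[nm]]@prefixSeq)
      expect_equal(back[[nm]]@suffixSeq, toy$linkerSeqs[[nm]]@suffixSeq)
      expect_equal(back[[nm]]@methylated, toy$linkerSeqs[[nm]]@methylated)
    }
  }
})
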