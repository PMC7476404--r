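test_that("deriveClips walks the circular alternation and deduplicates", {
  five <- constructDesign("c5", "A1",
    c("LMS", "bb", "LMP", "prom", "U1", "g1", "U2", "g2", "U3", "g3"))
  plan <- deriveClips(list(five))
  expect_equal(nrow(clips(plan)), 5L)
  # wrap-around: last part's suffix linker is the first design linker
  expect_equal(clips(plan)$suffix[5L], "LMS")
  expect_equal(clips(plan)$prefix[1L], "LMS")

  # listing the same design twice changes nothing
  twice <- deriveClips(list(five, constructDesign("c5b", "B1",
    designElements(five))))
  expect_equal(clips(twice), clips(plan))
  expect_equal(nrow(clips(twice)), 5L)

  # construct_refs preserve per-design clip order
  expect_equal(constructClips(plan)$c5, 1:5)
})

test_that("deriveClips equals a brute-force triple-set oracle on random sets", {
  for (seed in 1:20) {
    ds <- randomDesigns(seed)
    plan <- deriveClips(ds)
    keys <- sort(paste(clips(plan)$prefix, clips(plan)$part,
                       clips(plan)$suffix, sep = "|"))
    expect_equal(keys, bruteForceClipSet(ds))
    # |clips| <= total parts, equality iff no sharing
    totalParts <- sum(vapply(ds, function(d) length(designParts(d)), 1L))
    expect_lte(nrow(clips(plan)), totalParts)
    # determinism: same inputs, same order
    expect_identical(clips(deriveClips(ds)), clips(plan))
  }
})

test_that("capacity: 48 clips / 96 constructs pass, 49 / 97 fail", {
  # 2-part designs over disjoint names yield 2 new clips each
  mkNClips <- function(n) {
    designs <- lapply(seq_len(ceiling(n / 2)), function(i)
      constructDesign(paste0("d", i), indexToWell(i),
                      c(paste0("L", 2 * i - 1), paste0("p", i),
                        paste0("L", 2 * i), paste0("q", i))))
    plan <- deriveClips(designs)
    plan
  }
  expect_silent(checkCapacity(mkNClips(48L)))   # 24 designs, 48 clips
  expect_error(checkCapacity(mkNClips(49L)), class = "capacityError")

  emptyPlan <- deriveClips(list())
  expect_silent(checkCapacity(emptyPlan, nConstructs = 0L))   # vacuous
  expect_silent(checkCapacity(emptyPlan, nConstructs = 96L))
  expect_error(checkCapacity(emptyPlan, nConstructs = 97L),
               class = "capacityError")
})

test_that("clip well assignment: first A1, ninth A2, 48th H6, 49 errors", {
  mk <- function(nDesigns) lapply(seq_len(nDesigns), function(i)
    constructDesign(paste0("d", i), indexToWell(i),
                    c(paste0("L", 2 * i - 1), paste0("p", i),
                      paste0("L", 2 * i), paste0("q", i))))
  plan <- assignClipWells(deriveClips(mk(24L)))  # 48 clips
  w <- unname(clipWells(plan))
  expect_equal(w[1L], "A1")
  expect_equal(w[9L], "A2")
  expect_equal(w[48L], "H6")
  expect_true(all(wellColumn(w) <= 6L))
  expect_error(assignClipWells(deriveClips(mk(25L))), class = "capacityError")
})

test_that("clip volumes always conserve the 30 ul total", {
  plan <- deriveClips(list(toyDesign()))
  v <- clipVolumes(computeClipVolumes(plan))
  expect_equal(v$master_mix, c(20, 20))
  expect_equal(v$water, c(7, 7))  # 30 - 20 - 1 - 2x1
  expect_equal(unname(rowSums(v)), c(30, 30))

  # boundary: exactly zero water is allowed
  cfg <- basicConfig(overrides = list(clip = list(partVolume = 10,
                                                  linkerHalfVolume = 0)))
  v0 <- clipVolumes(computeClipVolumes(plan, cfg))
  expect_equal(v0$water, c(0, 0))
  expect_equal(unname(rowSums(v0)), c(30, 30))

  # negative water is a configuration error
  bad <- basicConfig(overrides = list(clip = list(partVolume = 12)))
  expect_error(computeClipVolumes(plan, bad), "configuration error")

  # conservation holds for random admissible configurations
  for (seed in 1:10) {
    set.seed(seed)
    pv <- round(runif(1, 0, 4), 1); lv <- round(runif(1, 0, 2), 1)
    cfgR <- basicConfig(overrides = list(clip = list(partVolume = pv,
                                                     linkerHalfVolume = lv)))
    vr <- clipVolumes(computeClipVolumes(plan, cfgR))
    expect_equal(unname(rowSums(vr)), rep(30, 2), tolerance = 1e-12)
  }
})

test_that("master mix recipe scales the printed per-reaction components", {
  one <- masterMixRecipe(1, excessFraction = 0)
  expect_equal(unname(one@perReaction),
               c(3, 1, 0.5, 15.5))
  expect_equal(sum(one@perReaction), 20)
  expect_equal(one@totals, one@perReaction)

  r38 <- masterMixRecipe(38, excessFraction = 0)
  expect_equal(unname(r38@totals), c(114, 38, 19, 589))
  expect_equal(sum(r38@totals), 38 * 20)

  r10 <- masterMixRecipe(10, excessFraction = 0)
  r10x <- masterMixRecipe(10, excessFraction = 0.1)
  expect_equal(r10x@totals, r10@totals * 1.1)

  expect_error(masterMixRecipe(0), "at least one")
})
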