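#' Factorial operon-library specification
#'
#' Describes a combinatorial three-gene operon library: each construct is
#' `LMS, backbone, LMP, promoter, UTR1-RBS, gene1, UTR2-RBS, gene2,
#' UTR3-RBS, gene3` — five parts and five linkers, circular. The RBS for
#' each gene rides on the UTR-RBS linker at that operon position, so the
#' linkers are functional parts of the design.
#'
#' Defaults expand 4 promoters x (3 GFP RBSs x 2 mCherry RBSs x 2 BFP
#' RBSs) x 2 gene orders = 96 combinations, minus the 8 combinations
#' pairing the weak J23105 promoter with the GFP RBS1 linker, leaving 88
#' constructs whose deduplicated clip set has 38 members. The default gene
#' orders are the rotated pair (sfGFP, mCherry, BFP) and (mCherry, BFP,
#' sfGFP): because UTR-RBS linkers are shared wherever the same RBS label
#' lands on the same operon position, the clip count depends on the order
#' pair, and the rotated pair is one of the two that yield 38 unique
#' clips. The orders and the 3/2/2 RBS split are configurable; promoter
#' names other than J23105 are arbitrary Anderson-series labels.
#'
#' @param promoters character vector of promoter part names.
#' @param rbsOptions named list: gene name -> character vector of RBS
#'   labels available for that gene.
#' @param geneOrders list of character vectors, each a permutation of the
#'   gene names.
#' @param exclusions list of `list(promoter=, gene=, rbs=)` combinations to
#'   drop (every construct matching all three is removed).
#' @param backbone backbone part name.
#' @param flanking the methylated flanking linkers, suffix then prefix
#'   side (`LMS`, `LMP`).
#' @return a `FactorialSpec` list.
#' @export
factorialSpec <- function(
    promoters = c("J23100", "J23104", "J23105", "J23108"),
    rbsOptions = list(sfGFP = c("RBS1", "RBS2", "RBS3"),
                      mCherry = c("RBS1", "RBS2"),
                      BFP = c("RBS1", "RBS2")),
    geneOrders = list(c("sfGFP", "mCherry", "BFP"),
                      c("mCherry", "BFP", "sfGFP")),
    exclusions = list(list(promoter = "J23105", gene = "sfGFP", rbs = "RBS1")),
    backbone = "p15A_cmR_backbone",
    flanking = c("LMS", "LMP")) {
  genes <- names(rbsOptions)
  stopifnot(length(genes) >= 1L, length(flanking) == 2L)
  for (ord in geneOrders)
    if (!setequal(ord, genes))
      stop("every gene order must be a permutation of names(rbsOptions)")
  structure(list(promoters = promoters, rbsOptions = rbsOptions,
                 geneOrders = geneOrders, exclusions = exclusions,
                 backbone = backbone, flanking = flanking),
            class = "FactorialSpec")
}

#' Expand a factorial specification into construct designs and plates
#'
#' Generates the full cartesian product (promoters x per-gene RBS choices
#' x gene orders) minus exclusions, assigns destination wells column-major
#' over columns 1-11 (leaving column 12 free for transformation
#' controls), and builds matching part and linker plate maps. With the
#' default [factorialSpec()] this reproduces the 88-construct library and
#' its 38 unique clip reactions.
#'
#' @param spec a [factorialSpec()].
#' @param outDir optional directory: the construct CSV and the two plate
#'   CSVs are written there.
#' @return list with `designs` (list of [ConstructDesign-class]),
#'   `partPlate`, `linkerPlate` ([PlateMap-class]), and `files` (paths,
#'   when `outDir` is given).
#' @examples
#' fx <- makeFactorialDesign()
#' length(fx$designs)  # 88
#' @export
makeFactorialDesign <- function(spec = factorialSpec(), outDir = NULL) {
  genes <- names(spec$rbsOptions)
  combos <- list()
  for (oi in seq_along(spec$geneOrders)) {
    ord <- spec$geneOrders[[oi]]
    grid <- expand.grid(c(list(promoter = spec$promoters),
                          stats::setNames(spec$rbsOptions[ord], ord)),
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid$order <- oi
    combos[[oi]] <- grid
  }
  designs <- list()
  for (oi in seq_along(combos)) {
    grid <- combos[[oi]]
    ord <- spec$geneOrders[[oi]]
    for (r in seq_len(nrow(grid))) {
      excluded <- any(vapply(spec$exclusions, function(e)
        grid$promoter[r] == e$promoter && e$gene %in% ord &&
          grid[[e$gene]][r] == e$rbs, TRUE))
      if (excluded) next
      rbs <- vapply(ord, function(g) grid[[g]][r], "")
      utrs <- sprintf("UTR%d-%s", seq_along(ord), rbs)
      elements <- c(spec$flanking[1L], spec$backbone, spec$flanking[2L],
                    grid$promoter[r],
                    as.vector(rbind(utrs, ord)))
      name <- paste(c(grid$promoter[r], sprintf("ord%d", oi),
                      sprintf("%s.%s", ord, rbs)), collapse = "_")
      designs[[length(designs) + 1L]] <- list(name = name, elements = elements)
    }
  }
  if (length(designs) > 96L)
    warning("specification expands to ", length(designs),
            " constructs; at most 96 fit one plate (the planner enforces ",
            "this, and only 88 leave column 12 free for controls)")
  wells <- indexToWell((seq_along(designs) - 1L) %% 96L + 1L)
  designs <- mapply(function(d, w) constructDesign(d$name, w, d$elements),
                    designs, wells, SIMPLIFY = FALSE)

  parts <- unique(unlist(lapply(designs, designParts)))
  linkers <- unique(unlist(lapply(designs, designLinkers)))
  partPlate <- plateMap("part_plate",
                        stats::setNames(indexToWell(seq_along(parts)), parts),
                        kind = "part")
  halves <- as.vector(rbind(paste0(linkers, "-P"), paste0(linkers, "-S")))
  linkerPlate <- plateMap("linker_plate",
                          stats::setNames(indexToWell(seq_along(halves)), halves),
                          kind = "linker")
  out <- list(designs = designs, partPlate = partPlate,
              linkerPlate = linkerPlate)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    files <- c(constructs = file.path(outDir, "constructs.csv"),
               parts = file.path(outDir, "part_plate.csv"),
               linkers = file.path(outDir, "linker_plate.csv"))
    writeConstructCsv(designs, files[["constructs"]])
    writePlateCsv(partPlate, files[["parts"]])
    writePlateCsv(linkerPlate, files[["linkers"]])
    out$files <- files
  }
  out
}

randomDna <- function(n, forbid = c("GGTCTC", "GAGACC")) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!any(vapply(forbid, grepl, TRUE, x = s, fixed = TRUE))) return(s)
  }
}

#' Generate a synthetic toy sequence library
#'
#' Builds seeded random part and linker sequences that satisfy the stored-
#' part grammar: every part sits in a circular storage vector flanked by a
#' Prefix (plus-strand recognition site, spacer, then the part's first
#' scar) and a Suffix (scar, spacer, minus-strand site); linkers have
#' unique 21-base tails shared letter-for-letter between their two halves
#' and no internal recognition sites. The two methylated flanking linkers
#' embed a regenerating Prefix (in the LMP prefix half, just upstream of
#' its scar) and Suffix (in the LMS suffix half, just downstream of its
#' scar), so assembled constructs are themselves valid stored parts.
#'
#' All sequences are synthetic stand-ins with the real structural grammar
#' (4-nt scars, 21-base tails, GGTCTC sites), not the published linker
#' set.
#'
#' @param seed integer seed; the library is byte-for-byte reproducible.
#' @param partNames,linkerNames names to generate sequences for.
#' @param methylated linker names to flag (and structure) as the
#'   Prefix/Suffix-recapitulating pair; the first is treated as the
#'   Suffix-side (LMS-like), the second as the Prefix-side (LMP-like).
#' @param coreLength part-core length (nt, excluding scars).
#' @param designs optional: 3 demo designs over the generated names are
#'   returned when TRUE.
#' @return list with `partSeqs`, `linkerSeqs` (named lists), `scarP`,
#'   `scarS`, and optionally `designs`.
#' @export
makeToyLibrary <- function(seed = 0L,
                           partNames = c("backbone", "promoterA", "geneX",
                                         "geneY"),
                           linkerNames = c("LMS", "LMP", "L1", "L2", "L3"),
                           methylated = c("LMS", "LMP"),
                           coreLength = 60L,
                           designs = TRUE) {
  stopifnot(length(methylated) == 2L)
  set.seed(as.integer(seed))
  model <- restrictionModel()
  nMotifs <- function(s, circular = FALSE)
    nrow(findRecognitionSites(s, model, circular = circular))
  scarP <- randomDna(4L)
  scarS <- randomDna(4L)
  while (scarS == scarP) scarS <- randomDna(4L)

  tails <- character(0)
  linkerSeqs <- list()
  for (nm in linkerNames) {
    repeat {
      tail <- randomDna(21L)
      if (!tail %in% tails && !revcomp(tail) %in% tails) break
    }
    tails <- c(tails, tail)
    isLMS <- nm == methylated[1L]
    isLMP <- nm == methylated[2L]
    repeat {
      pCore <- if (isLMP) paste0(randomDna(8L), "GGTCTC", "A") else randomDna(10L)
      sCore <- if (isLMS) paste0("T", "GAGACC", randomDna(8L)) else randomDna(10L)
      pSeq <- paste0(tail, pCore, scarP)
      sSeq <- paste0(scarS, sCore, tail)
      # no stray recognition motifs beyond the planted ones
      if (nMotifs(pSeq) == as.integer(isLMP) &&
          nMotifs(sSeq) == as.integer(isLMS)) break
    }
    linkerSeqs[[nm]] <- linkerSequence(nm, prefixSeq = pSeq, suffixSeq = sSeq,
                                       methylated = isLMS || isLMP)
  }

  partSeqs <- list()
  for (nm in partNames) {
    repeat {
      inner <- randomDna(coreLength)
      core <- paste0(scarP, inner, scarS)
      vec <- paste0(randomDna(40L), "GGTCTC", "A", core, "T", "GAGACC",
                    randomDna(40L))
      if (nMotifs(vec, circular = TRUE) == 2L) break
    }
    partSeqs[[nm]] <- partSequence(nm, vec, topology = "circular")
  }

  out <- list(partSeqs = partSeqs, linkerSeqs = linkerSeqs,
              scarP = scarP, scarS = scarS)
  if (isTRUE(designs) && length(partNames) >= 4L && length(linkerNames) >= 5L &&
      all(methylated %in% linkerNames)) {
    other <- setdiff(linkerNames, methylated)
    out$designs <- list(
      constructDesign("toy1", "A1",
        c(methylated[1L], partNames[1L], methylated[2L], partNames[2L],
          other[1L], partNames[3L])),
      constructDesign("toy2", "B1",
        c(methylated[1L], partNames[1L], methylated[2L], partNames[2L],
          other[1L], partNames[4L])),
      constructDesign("toy3", "C1",
        c(methylated[1L], partNames[1L], methylated[2L], partNames[3L],
          other[2L], partNames[4L])))
  }
  out
}

#' Toy sequences for an arbitrary design set
#'
#' Convenience wrapper over [makeToyLibrary()]: generates sequences for
#' exactly the part and linker names a design list uses.
#'
#' @param designs list of [ConstructDesign-class].
#' @param seed integer seed.
#' @param methylated the two flanking linker names (Suffix-side first).
#' @param coreLength part-core length.
#' @return as [makeToyLibrary()] (without demo designs).
#' @export
toySequencesFor <- function(designs, seed = 0L,
                            methylated = c("LMS", "LMP"),
                            coreLength = 60L) {
  makeToyLibrary(seed = seed,
                 partNames = unique(unlist(lapply(designs, designParts))),
                 linkerNames = unique(unlist(lapply(designs, designLinkers))),
                 methylated = methylated, coreLength = coreLength,
                 designs = FALSE)
}
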