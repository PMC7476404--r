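# Shared fixture builders; everything is generated in code at test time.

toyDesign <- function(name = "toy", well = "A1",
                      elements = c("LMS", "backbone", "LMP", "insert")) {
  constructDesign(name, well, elements)
}

toyPlates <- function(designs) {
  parts <- unique(unlist(lapply(designs, designParts)))
  linkers <- unique(unlist(lapply(designs, designLinkers)))
  halves <- as.vector(rbind(paste0(linkers, "-P"), paste0(linkers, "-S")))
  list(
    parts = plateMap("parts", setNames(indexToWell(seq_along(parts)), parts),
                     kind = "part"),
    linkers = plateMap("linkers",
                       setNames(indexToWell(seq_along(halves)), halves),
                       kind = "linker"))
}

# random design sets for property tests: <= nDesigns designs, 2-6 parts
# each, linkers sampled without replacement within a design
randomDesigns <- function(seed, nDesigns = 8L, maxParts = 6L) {
  set.seed(seed)
  linkPool <- paste0("L", 1:10)
  partPool <- paste0("P", 1:8)
  n <- sample.int(nDesigns, 1L)
  lapply(seq_len(n), function(i) {
    k <- sample(2:maxParts, 1L)
    linkers <- sample(linkPool, k)
    parts <- sample(partPool, k, replace = TRUE)
    constructDesign(paste0("d", i), indexToWell(i),
                    as.vector(rbind(linkers, parts)))
  })
}

# independent brute-force clip enumeration: collect every
# (previous linker, part, next linker) triple into a set
bruteForceClipSet <- function(designs) {
  triples <- character()
  for (d in designs) {
    el <- designElements(d)
    n <- length(el)
    for (pPos in seq(2L, n, by = 2L)) {
      nxt <- if (pPos == n) el[1L] else el[pPos + 1L]
      triples <- c(triples, paste(el[pPos - 1L], el[pPos], nxt, sep = "|"))
    }
  }
  sort(unique(triples))
}

# full linker plus-strand text: suffix half overlapped with prefix half
# at the shared 21-base tail
fullLinkerText <- function(linker) {
  paste0(linker@suffixSeq, substring(linker@prefixSeq, linker@tailLength + 1L))
}

# concatenation oracle: join plus-strand pieces overlapping by `ov` bases
joinByOverlap <- function(pieces, ov = 4L) {
  out <- pieces[[1L]]
  for (p in pieces[-1L]) {
    stopifnot(substring(out, nchar(out) - ov + 1L) == substr(p, 1L, ov))
    out <- paste0(out, substring(p, ov + 1L))
  }
  out
}

# expected circular construct text for a design, built purely by string
# concatenation of part cores and full linker texts (independent of the
# fragment/annealing machinery)
oracleConstructText <- function(design, toy) {
  el <- designElements(design)
  n <- length(el)
  pieces <- list()
  for (pPos in seq(2L, n, by = 2L)) {
    coreSeq <- oraclePartCore(toy$partSeqs[[el[pPos]]])
    nxtLinker <- if (pPos == n) el[1L] else el[pPos + 1L]
    pieces <- c(pieces, coreSeq, fullLinkerText(toy$linkerSeqs[[nxtLinker]]))
  }
  circ <- joinByOverlap(pieces, 4L)
  # close the circle: last linker text ends with the scar that opens the
  # first part core; drop the duplicated 4-mer
  stopifnot(substring(circ, nchar(circ) - 3L) == substr(circ, 1L, 4L))
  substr(circ, 1L, nchar(circ) - 4L)
}

# part core by direct string surgery on the generated storage vector
# (mirror of how makeToyLibrary plants the sites; no restriction scanning)
oraclePartCore <- function(part) {
  s <- part@seq
  p <- regexpr("GGTCTC", s, fixed = TRUE)
  q <- regexpr("GAGACC", s, fixed = TRUE)
  substr(s, p + 7L, q - 2L)
}

rotateTo <- function(circ, anchor) {
  i <- regexpr(anchor, paste0(circ, circ), fixed = TRUE)
  stopifnot(i > 0L)
  shift <- (i - 1L) %% nchar(circ)
  paste0(substring(circ, shift + 1L), substr(circ, 1L, shift))
}
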