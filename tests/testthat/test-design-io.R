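test_that("well addressing is column-major A1..H12 without padding", {
  expect_equal(wellAddress(c("a1", "H12", " B03 ")), c("A1", "H12", "B3"))
  expect_equal(wellIndex("A1"), 1L)
  expect_equal(wellIndex("A2"), 9L)
  expect_equal(indexToWell(48L), "H6")
  expect_equal(indexToWell(wellIndex(c("C7", "H12"))), c("C7", "H12"))
  expect_error(wellAddress("I1"), "invalid well")
  expect_error(wellAddress("A13"), "out of range")
})

test_that("construct CSV parsing handles toy rows, empty bodies and errors", {
  txt <- c("name,well,e1,e2,e3,e4", "C1,A1,LMS,backbone,LMP,insert")
  d <- parseConstructCsv(txt)
  expect_length(d, 1L)
  expect_equal(designName(d[[1]]), "C1")
  expect_equal(designElements(d[[1]]), c("LMS", "backbone", "LMP", "insert"))
  expect_equal(designLinkers(d[[1]]), c("LMS", "LMP"))
  expect_equal(designParts(d[[1]]), c("backbone", "insert"))

  # header only -> empty list, not an error
  expect_equal(parseConstructCsv("name,well"), list())

  # odd element count names the offending row
  expect_error(parseConstructCsv(c("h", "C1,A1,LMS,backbone,LMP")),
               "malformed alternation")
  # duplicate destination wells conflict
  expect_error(parseConstructCsv(c("h", "C1,A1,L1,p,L2,q", "C2,A1,L1,p,L3,q")),
               "duplicate destination well")
})

test_that("construct CSV writer round-trips parsed designs exactly", {
  designs <- list(
    toyDesign("C1", "A1"),
    toyDesign("C2", "B1", c("LMS", "backbone", "LMP", "geneA", "L1", "geneB")))
  reparsed <- parseConstructCsv(writeConstructCsv(designs))
  expect_length(reparsed, 2L)
  for (i in seq_along(designs)) {
    expect_equal(designName(reparsed[[i]]), designName(designs[[i]]))
    expect_equal(destinationWell(reparsed[[i]]), destinationWell(designs[[i]]))
    expect_equal(designElements(reparsed[[i]]), designElements(designs[[i]]))
  }

  # randomized round-trip property
  for (seed in 1:5) {
    ds <- randomDesigns(seed)
    rp <- parseConstructCsv(writeConstructCsv(ds))
    expect_equal(lapply(rp, designElements), lapply(ds, designElements))
    expect_equal(vapply(rp, destinationWell, ""),
                 vapply(ds, destinationWell, ""))
  }
})

test_that("plate CSV parsing maps reagents and pairs linker halves", {
  p <- parsePlateCsv(c("name,well", "sfGFP,A3"), kind = "part")
  expect_equal(reagentWell(p, "sfGFP"), "A3")

  l <- parsePlateCsv(c("name,well", "L1-P,A1", "L1-S,B1"), kind = "linker")
  h <- linkerHalves(l)
  expect_equal(h$linker, c("L1", "L1"))
  expect_equal(h$well[h$half == "prefix"], "A1")
  expect_equal(h$well[h$half == "suffix"], "B1")

  expect_error(parsePlateCsv(c("name,well", "L1,A1"), kind = "linker"),
               "-P' or '<linker>-S")
  expect_error(plateMap("p", c(a = "A1", b = "A1")), "share well")

  # writer round-trip
  rt <- parsePlateCsv(writePlateCsv(p), kind = "part")
  expect_equal(plateEntries(rt), plateEntries(p))
})

test_that("validateDesigns classifies errors and warnings deterministically", {
  designs <- list(toyDesign("C1", "A1"))
  plates <- toyPlates(designs)
  expect_equal(nrow(validateDesigns(designs, plates$parts, plates$linkers)), 0L)

  # unknown part
  bad <- list(toyDesign("C1", "A1", c("LMS", "mCherry2", "LMP", "insert")))
  iss <- validateDesigns(bad, plates$parts, plates$linkers)
  err <- iss[iss$severity == "error", ]
  expect_equal(err$code, "unknown_reagent")
  expect_match(err$message, "mCherry2")

  # part name in a linker slot
  bad2 <- list(toyDesign("C1", "A1", c("LMS", "backbone", "insert", "backbone")))
  iss2 <- validateDesigns(bad2, plates$parts, plates$linkers)
  expect_true("alternation" %in% iss2$code)

  # missing linker half
  halfless <- plateMap("linkers", c(`LMS-P` = "A1", `LMS-S` = "B1",
                                    `LMP-P` = "C1"), kind = "linker")
  iss3 <- validateDesigns(designs, plates$parts, halfless)
  expect_true("missing_half" %in% iss3$code)

  # unused reagents warn, purity: identical inputs -> identical output
  extra <- plateMap("parts", c(backbone = "A1", insert = "B1", spare = "C1"),
                    kind = "part")
  iss4 <- validateDesigns(designs, extra, plates$linkers)
  expect_equal(iss4$severity, "warning")
  expect_identical(iss4, validateDesigns(designs, extra, plates$linkers))
})

test_that("sequence IO enforces the alphabet and round-trips GenBank topology", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">rec1", paste(rep("ACGT", 25), collapse = "")), fa)
  seqs <- readSequences(fa)
  expect_length(seqs, 1L)
  expect_equal(nchar(seqs$rec1@seq), 100L)
  expect_equal(seqs$rec1@topology, "linear")

  writeLines(c(">bad", "ACGTN"), fa)
  expect_error(readSequences(fa), "alphabet error")

  gb <- tempfile(fileext = ".gb")
  feats <- data.frame(start = 0L, end = 40L, type = "part", label = "toy",
                      stringsAsFactors = FALSE)
  seq <- paste(rep("GATTACA", 20), collapse = "")
  writeGenbankRecord("plasmid1", seq, gb, circular = TRUE, features = feats)
  back <- readGenbank(gb)[["plasmid1"]]
  expect_true(back$circular)
  expect_equal(back$seq, seq)
  expect_equal(back$features$start, 0L)
  expect_equal(back$features$end, 40L)
  expect_equal(back$features$label, "toy")

  # linear flag round-trips too
  writeGenbankRecord("lin1", seq, gb, circular = FALSE)
  expect_false(readGenbank(gb)[["lin1"]]$circular)

  # duplicate record names across files conflict
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">lin1", "ACGTACGT"), fa2)
  expect_error(readSequences(c(gb, fa2)), "duplicate record name")
})

test_that("written GenBank is readable by an independent parser", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  gb <- tempfile(fileext = ".gb")
  seq <- paste(rep("ACGTTGCA", 30), collapse = "")
  writeGenbankRecord("xcheck", seq, gb, circular = TRUE,
                     features = data.frame(start = 4L, end = 64L,
                                           type = "linker", label = "L1"))
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "from Bio import SeqIO; r = SeqIO.read('", gb, "', 'genbank'); ",
    "print(len(r.seq), str(r.seq[:8]), r.annotations.get('topology', ''))"
  ))), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  skip_if(!is.null(status) && status != 0, "biopython unavailable")
  expect_match(paste(out, collapse = " "), "240 ACGTTGCA circular")
})
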