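axtFixture <- function() {
  c("0 chr1 11 19 chrA 1 9 + 100",
    "ACGTACGTA",
    "ACGTACGTA",
    "",
    "1 chr2 5 10 chrB 3 9 - 55",
    "AC--GTAC",
    "ACGTGT-C",
    "")
}

test_that("readAxt parses blocks, normalizes case and round-trips", {
  f <- withr::local_tempfile(fileext = ".axt")
  writeLines(axtFixture(), f)
  alns <- readAxt(f)
  expect_length(alns, 2L)
  expect_equal(alignmentLength(alns[[1]]), 9L)
  expect_equal(targetSeq(alns[[2]]), "AC--GTAC")
  expect_equal(alns[[1]]@targetStart, 11L)
  expect_equal(alns[[2]]@infoStrand, "-")
  # lower-case input is upper-cased
  f2 <- withr::local_tempfile(fileext = ".axt")
  writeLines(c("0 chr1 1 3 chrA 1 3 + 5", "acg", "tgc", ""), f2)
  expect_equal(targetSeq(readAxt(f2)[[1]]), "ACG")
  # write -> read -> write round-trips byte-identically
  f3 <- withr::local_tempfile(fileext = ".axt")
  writeAxt(alns, f3)
  expect_identical(readLines(f3), axtFixture())
  f4 <- withr::local_tempfile(fileext = ".axt")
  writeAxt(readAxt(f3), f4)
  expect_identical(readLines(f4), readLines(f3))
})

test_that("readAxt rejects malformed blocks with the block index", {
  bad <- function(lines) {
    f <- withr::local_tempfile(fileext = ".axt",
                               .local_envir = parent.frame())
    writeLines(lines, f)
    f
  }
  expect_length(readAxt(bad(character(0))), 0L)
  expect_error(readAxt(bad(c("0 chr1 1 3 chrA 1 3 + 5", "ACG", "TGCA", ""))),
               "block 1.*length")
  expect_error(readAxt(bad(c("0 chr1 1 3 chrA 1 3 +", "ACG", "TGC", ""))),
               "fields")
  expect_error(readAxt(bad(c("0 chr1 one 3 chrA 1 3 + 5", "ACG", "TGC", ""))),
               "non-numeric")
  expect_error(readAxt(bad(c("0 chr1 1 3 chrA 1 3 + 5", "AXG", "TGC", ""))),
               "block 1")
  # second block malformed is reported as block 2
  expect_error(readAxt(bad(c("0 chr1 1 3 chrA 1 3 + 5", "ACG", "TGC", "",
                             "1 chr1 1 3 chrA 1 3 + 5", "ACGT", "TGC", ""))),
               "block 2")
})

test_that("AlignmentPair validity enforces the column invariants", {
  expect_error(AlignmentPair("A-GT", "T-CA"), "gapped in both")
  expect_error(new("AlignmentPair", targetName = "c", targetStart = 1L,
                   targetEnd = 9L, infoName = "c", infoStart = 1L,
                   infoEnd = 3L, infoStrand = "+", score = 0,
                   targetSeq = "ACG", infoSeq = "TTT"),
               "span")
  aln <- AlignmentPair("AC--GTAC", "ACGTGT-C", targetStart = 5)
  expect_equal(aln@targetEnd, 10L) # 6 non-gap characters from 5
})

test_that("reverseComplement complements, flips strand and is an involution", {
  aln <- AlignmentPair("ACG-T", "AC-TT")
  rc <- reverseComplement(aln)
  expect_equal(targetSeq(rc), "A-CGT")
  expect_equal(infoSeq(rc), "AA-GT")
  expect_equal(rc@infoStrand, "-")
  expect_equal(reverseComplement(rc), aln)
  # N is a fixed point
  nn <- AlignmentPair("NNN", "NNN")
  expect_equal(targetSeq(reverseComplement(nn)), "NNN")
  # involution and column-count preservation on random alignments
  for (s in 1:10) {
    a <- randomAlignmentPair(31, seed = s)
    rc <- reverseComplement(a)
    expect_equal(alignmentLength(rc), 31L)
    expect_equal(reverseComplement(rc), a)
    expect_equal(targetSeq(rc), oracleRevComp(targetSeq(a)))
  }
})

test_that("filterByLength keeps strictly longer alignments only", {
  a150 <- randomAlignmentPair(150, seed = 1)
  a151 <- randomAlignmentPair(151, seed = 2)
  expect_identical(filterByLength(list(a150, a151)), list(a151))
  expect_length(filterByLength(list(a150, a151), minLen = 0), 2L)
  expect_identical(filterByLength(list(), 150), list())
})

test_that("writeResults emits the BED coordinate convention and scores", {
  res <- data.frame(
    id = c("a", "b", "c"), targetName = "chr1",
    targetStart = c(11L, 1L, 2L), targetEnd = c(19L, 50L, 60L),
    strand = c("+", "-", NA), offset = c(0L, 1L, NA),
    blockStart = c(1L, 1L, NA), sHat = c(1.2, NA, NA),
    nScores = c(30L, 30L, NA), p = c(0.001, 1, NA), q = c(0.002, 1, NA),
    status = c("tested", "tested", "skipped"), stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeResults(res, tsv, bed, qThreshold = 1)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3L)
  bedLines <- read.table(bed, sep = "\t")
  # 1-based inclusive 11..19 becomes 0-based half-open 10..19
  expect_equal(unlist(bedLines[1, 2:3], use.names = FALSE), c(10L, 19L))
  expect_true(all(bedLines$V2 >= 0 & bedLines$V2 < bedLines$V3))
  expect_equal(bedLines$V5, c(300L, 0L)) # -100*log10(p); p = 1 gives 0
  # empty results: header-only TSV, empty BED
  writeResults(res[0, ], tsv, bed)
  expect_equal(length(readLines(tsv)), 1L)
  expect_equal(length(readLines(bed)), 0L)
})
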