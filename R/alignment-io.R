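#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Read pairwise alignments from an AXT file
#'
#' Parses UCSC AXT blocks: a summary line
#' `index tName tStart tEnd qName qStart qEnd qStrand score` followed by the
#' target and information sequence lines, blocks separated by blank lines.
#' Coordinates are taken as 1-based inclusive; sequences are upper-cased.
#'
#' @param file path or connection to an AXT stream.
#' @return a list of [AlignmentPair-class] objects in file order (empty
#'   list for an empty stream).
#' @examples
#' axt <- tempfile(fileext = ".axt")
#' writeLines(c("0 chr1 11 19 chrA 1 9 + 100", "ACGTACGTA", "ACGTACGTA", ""),
#'            axt)
#' readAxt(axt)
#' @seealso [writeAxt()]
#' @export
readAxt <- function(file) {
  lines <- readLines(file)
  # drop comment lines (some AXT files carry a '#' header)
  lines <- lines[!startsWith(lines, "#")]
  nonEmpty <- which(nzchar(lines))
  if (!length(nonEmpty)) return(list())
  # group consecutive non-empty lines into blocks
  grp <- cumsum(c(TRUE, diff(nonEmpty) > 1L))
  blocks <- split(lines[nonEmpty], grp)
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    if (length(bl) != 3L)
      stop(sprintf("AXT block %d: expected 3 lines, found %d", b, length(bl)),
           call. = FALSE)
    fields <- strsplit(trimws(bl[1L]), "[ \t]+")[[1L]]
    if (length(fields) != 9L)
      stop(sprintf("AXT block %d: summary line has %d fields, expected 9",
                   b, length(fields)), call. = FALSE)
    nums <- suppressWarnings(as.integer(fields[c(1L, 3L, 4L, 6L, 7L, 9L)]))
    if (anyNA(nums))
      stop(sprintf("AXT block %d: non-numeric coordinate or score", b),
           call. = FALSE)
    if (nchar(bl[2L]) != nchar(bl[3L]))
      stop(sprintf("AXT block %d: sequence lines differ in length", b),
           call. = FALSE)
    aln <- tryCatch(
      AlignmentPair(targetSeq = bl[2L], infoSeq = bl[3L],
                    targetName = fields[2L], targetStart = nums[2L],
                    targetEnd = nums[3L],
                    infoName = fields[5L], infoStart = nums[4L],
                    infoEnd = nums[5L],
                    infoStrand = fields[8L], score = nums[6L]),
      error = function(e)
        stop(sprintf("AXT block %d: %s", b, conditionMessage(e)),
             call. = FALSE))
    out[[b]] <- aln
  }
  out
}

#' Write pairwise alignments as AXT
#'
#' Emits one AXT block per alignment (summary line, two sequence lines and
#' a blank separator), numbering blocks from 0 in list order.  Output of
#' `writeAxt()` re-read with [readAxt()] round-trips byte-identically.
#'
#' @param alns list of [AlignmentPair-class] objects.
#' @param file output path or connection.
#' @return `file`, invisibly.
#' @export
writeAxt <- function(alns, file) {
  lines <- unlist(lapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    c(sprintf("%d %s %d %d %s %d %d %s %d", i - 1L, a@targetName,
              a@targetStart, a@targetEnd, a@infoName, a@infoStart,
              a@infoEnd, a@infoStrand, as.integer(a@score)),
      a@targetSeq, a@infoSeq, "")
  }))
  writeLines(as.character(lines), file)
  invisible(file)
}

#' Reverse-complement an alignment
#'
#' Both sequences are reversed and complemented (`A<->T`, `G<->C`, `N` and
#' `-` unchanged); the information-strand marker is flipped and all
#' coordinates are carried unchanged.  The operation is an involution.
#'
#' @param x an [AlignmentPair-class].
#' @return the reverse-complemented [AlignmentPair-class].
#' @examples
#' reverseComplement(AlignmentPair("ACG-T", "AC-TT"))
#' @importFrom Biostrings reverseComplement
#' @export
#' @aliases reverseComplement
setMethod("reverseComplement", "AlignmentPair", function(x, ...) {
  rc <- function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
  initialize(x,
             targetSeq = rc(x@targetSeq), infoSeq = rc(x@infoSeq),
             infoStrand = if (x@infoStrand == "+") "-" else "+")
})

#' Keep alignments longer than a column threshold
#'
#' Retains alignments whose column count (gaps included) is strictly
#' greater than `minLen`; the default reproduces the reference pipeline's
#' "longer than 150 bp" input filter.
#'
#' @param alns list of [AlignmentPair-class] objects.
#' @param minLen minimum column count (exclusive); non-negative.
#' @return the filtered list.
#' @export
filterByLength <- function(alns, minLen = 150L) {
  stopifnot(minLen >= 0)
  alns[vapply(alns, alignmentLength, integer(1)) > minLen]
}

#' Write test results as TSV and BED
#'
#' The TSV carries one row per input alignment (including skipped ones)
#' with all floating point values printed to 6 significant digits.  The
#' BED (0-based, half-open) contains the target intervals of tested
#' alignments with `q <= qThreshold`; the BED score is
#' `min(1000, round(-100 * log10(p)))`.
#'
#' @param results data frame from [scoreAlignments()].
#' @param tsvFile,bedFile output paths (or connections for the TSV).
#' @param qThreshold q-value cutoff for BED inclusion.
#' @return invisibly, the number of BED intervals written.
#' @export
writeResults <- function(results, tsvFile, bedFile, qThreshold = 0.05) {
  out <- results
  for (col in c("sHat", "p", "q"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(signif(out[[col]], 6), format = "g",
                                 digits = 6))
  utils::write.table(out, tsvFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hit <- !is.na(results$q) & results$status == "tested" &
    results$q <= qThreshold
  bed <- results[hit, , drop = FALSE]
  if (nrow(bed)) {
    score <- pmin(1000, round(-100 * log10(bed$p)))
    bedLines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", bed$targetName,
                        bed$targetStart - 1L, bed$targetEnd, bed$id,
                        as.integer(score), bed$strand)
  } else bedLines <- character(0)
  writeLines(bedLines, bedFile)
  invisible(length(bedLines))
}
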