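#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Encode and decode nucleotide triplets
#'
#' Triplets over the 5-letter alphabet `A=0, T=1, G=2, C=3, indel=4` are
#' coded as the base-5 integer `25*c1 + 5*c2 + c3` in `[0, 124]`.  `N` is
#' treated as the indel symbol, keeping the alphabet closed.
#' `decodeTriplet()` inverts the map (codes containing digit 4 decode to
#' `-`).
#'
#' @param x character vector of 3-letter triplets (e.g. `"CTG"`).
#' @return integer codes for `encodeTriplet()`; triplet strings for
#'   `decodeTriplet()`.
#' @examples
#' encodeTriplet(c("AAA", "CTG", "---")) # 0, 82, 124
#' decodeTriplet(82)
#' @export
encodeTriplet <- function(x) {
  if (any(nchar(x) != 3L))
    stop("triplets must have exactly 3 characters", call. = FALSE)
  vapply(x, function(s) {
    d <- .encodeSeq(toupper(s))
    25L * d[1L] + 5L * d[2L] + d[3L]
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname encodeTriplet
#' @param code integer vector of triplet codes in `[0, 124]`.
#' @export
decodeTriplet <- function(code) {
  if (any(code < 0L | code > 124L))
    stop("triplet codes must lie in [0, 124]", call. = FALSE)
  d <- .DIGITS[code + 1L, , drop = FALSE]
  paste0(.SYMBOLS[d[, 1L] + 1L], .SYMBOLS[d[, 2L] + 1L],
         .SYMBOLS[d[, 3L] + 1L])
}

#' Segment an alignment into aligned triplet pairs
#'
#' Applies one framing: on the reverse strand the alignment is first
#' reverse-complemented; then the first `offset` columns are skipped and
#' the remaining columns are grouped into consecutive non-overlapping
#' triples, dropping any partial triplet at the end.  Target-sequence
#' characters give the `h` codes and information-sequence characters the
#' aligned `m` codes.
#'
#' @param aln an [AlignmentPair-class].
#' @param strand `"+"` or `"-"`.
#' @param offset frame offset, 0, 1 or 2.
#' @return a [TripletFrame-class].
#' @examples
#' frameAlignment(AlignmentPair("ACGTACGTA", "ACGTACGTA"))
#' @export
frameAlignment <- function(aln, strand = "+", offset = 0L) {
  stopifnot(strand %in% c("+", "-"), offset %in% 0:2)
  if (strand == "-") aln <- reverseComplement(aln)
  dt <- .encodeSeq(aln@targetSeq)
  di <- .encodeSeq(aln@infoSeq)
  h <- .digitsToCodes(dt, offset)
  if (!length(h))
    stop(sprintf("alignment too short to frame: %d columns at offset %d",
                 length(dt), offset), call. = FALSE)
  m <- .digitsToCodes(di, offset)
  new("TripletFrame", h = h, m = m, strand = strand,
      offset = as.integer(offset), firstColumn = as.integer(offset + 1L),
      lastColumn = as.integer(offset + 3L * length(h)))
}

# tally adjacent-pair counts (left code -> right code) into a 125x125 matrix
.countAdjacent <- function(frames) {
  tab <- numeric(15625L)
  for (fr in frames) {
    h <- fr@h
    L <- length(h)
    if (L < 2L) next
    idx <- 125L * h[-L] + h[-1L] + 1L
    tab <- tab + tabulate(idx, nbins = 15625L)
  }
  matrix(tab, nrow = 125L, byrow = TRUE)
}

# tally aligned-pair counts (target code -> info code)
.countAligned <- function(frames) {
  tab <- numeric(15625L)
  for (fr in frames) {
    if (!length(fr@h)) next
    idx <- 125L * fr@h + fr@m + 1L
    tab <- tab + tabulate(idx, nbins = 15625L)
  }
  matrix(tab, nrow = 125L, byrow = TRUE)
}

.pseudoNormalize <- function(counts, e) {
  # (count + e) / (row count + 125 e); denominator recycles per row
  (counts + e) / (rowSums(counts) + 125 * e)
}

#' Estimate the codon and background probability tables
#'
#' Pseudocount estimation of the four conditional tables from framed
#' training alignments: for the codon tables, `PA[h', h]` is
#' `(N(h'h) + e) / (N(h') + 125 e)` over adjacent triplet pairs of the
#' coding series (which must be in known codon frame), and `PB[h, m]`
#' analogous over aligned pairs; `QA`/`QB` are computed identically from
#' the noncoding series.  With no training data every entry is `1/125`.
#'
#' @param codingFrames,noncodingFrames lists of [TripletFrame-class]
#'   objects (may be empty).
#' @param pseudocount positive pseudocount `e` (default 1).
#' @return a [CodonModel-class].
#' @seealso [frameAlignment()], [trainCodonModel()]
#' @export
estimateMatrices <- function(codingFrames, noncodingFrames,
                             pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a positive number", call. = FALSE)
  CodonModel(
    PA = .pseudoNormalize(.countAdjacent(codingFrames), pseudocount),
    PB = .pseudoNormalize(.countAligned(codingFrames), pseudocount),
    QA = .pseudoNormalize(.countAdjacent(noncodingFrames), pseudocount),
    QB = .pseudoNormalize(.countAligned(noncodingFrames), pseudocount),
    pseudocount = pseudocount)
}

#' Serialize a CodonModel as plain text
#'
#' Writes a small header followed by the four tables, each introduced by a
#' `> NAME` line and laid out as 125 rows of 125 numbers in triplet-code
#' order.  `readCodonModel()` parses the same format.  Writing is
#' deterministic: identical models produce byte-identical files.
#'
#' @param model a [CodonModel-class].
#' @param file path to write to / read from.
#' @return `writeCodonModel()` returns `file` invisibly;
#'   `readCodonModel()` a [CodonModel-class].
#' @export
writeCodonModel <- function(model, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# CodonModel probability tables",
               "# alphabet: A=0 T=1 G=2 C=3 indel=4; code = 25*c1 + 5*c2 + c3",
               sprintf("# pseudocount: %s", format(model@pseudocount))), con)
  for (nm in c("PA", "PB", "QA", "QB")) {
    writeLines(paste0("> ", nm), con)
    mat <- slot(model, nm)
    writeLines(apply(mat, 1L, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  }
  invisible(file)
}

#' @rdname writeCodonModel
#' @export
readCodonModel <- function(file) {
  lines <- readLines(file)
  pc <- NA_real_
  pcLine <- grep("^# pseudocount:", lines, value = TRUE)
  if (length(pcLine))
    pc <- suppressWarnings(as.numeric(sub("^# pseudocount:\\s*", "",
                                          pcLine[1L])))
  lines <- lines[!startsWith(lines, "#")]
  starts <- grep("^> ", lines)
  if (length(starts) != 4L)
    stop("model file must contain exactly 4 tables", call. = FALSE)
  tabs <- list()
  for (k in seq_along(starts)) {
    nm <- sub("^> ", "", lines[starts[k]])
    rows <- lines[(starts[k] + 1L):(starts[k] + 125L)]
    vals <- scan(text = rows, quiet = TRUE)
    tabs[[nm]] <- matrix(vals, nrow = 125L, byrow = TRUE)
  }
  CodonModel(PA = tabs$PA, PB = tabs$PB, QA = tabs$QA, QB = tabs$QB,
             pseudocount = pc)
}
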