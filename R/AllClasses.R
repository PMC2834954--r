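#' @import methods
NULL

.AXT_ALPHABET <- "^[ACGTN-]*$"

.seqCharCodes <- function(s) utf8ToInt(s)

#' AlignmentPair: a gapped pairwise genomic alignment
#'
#' Holds one gapped alignment between a *target* sequence (the genome under
#' test) and an *information* sequence (the aligned related-species genome
#' that supplies the conservation signal), together with the genomic
#' coordinates carried by AXT records.  Coordinates are 1-based and inclusive
#' on both sequences; the two sequence strings have equal length and columns
#' gapped in both sequences are forbidden.
#'
#' @slot targetName chromosome/contig id of the target sequence.
#' @slot targetStart,targetEnd 1-based inclusive genomic coordinates; the
#'   span equals the number of non-gap characters in `targetSeq`.
#' @slot infoName,infoStart,infoEnd same for the information sequence.
#' @slot infoStrand `"+"` or `"-"`; flipped by [reverseComplement()].
#' @slot score integer alignment score, passed through unchanged.
#' @slot targetSeq,infoSeq equal-length strings over `A,C,G,T,N,-`
#'   (upper case).
#'
#' @seealso [readAxt()], [reverseComplement()], [frameAlignment()]
#' @export
setClass("AlignmentPair",
  representation(
    targetName = "character",
    targetStart = "integer",
    targetEnd = "integer",
    infoName = "character",
    infoStart = "integer",
    infoEnd = "integer",
    infoStrand = "character",
    score = "numeric",
    targetSeq = "character",
    infoSeq = "character"
  ),
  prototype(
    targetName = "chrT", targetStart = 1L, targetEnd = 0L,
    infoName = "chrI", infoStart = 1L, infoEnd = 0L,
    infoStrand = "+", score = 0, targetSeq = "", infoSeq = ""
  )
)

setValidity("AlignmentPair", function(object) {
  msg <- character(0)
  one <- function(x) length(x) == 1L && !is.na(x)
  if (!all(vapply(list(object@targetName, object@infoName, object@infoStrand,
                       object@targetSeq, object@infoSeq), one, logical(1))))
    return("all slots must be length-1 and non-NA")
  ts <- object@targetSeq
  is <- object@infoSeq
  if (nchar(ts) != nchar(is))
    msg <- c(msg, "target and information sequences differ in length")
  if (!grepl(.AXT_ALPHABET, ts) || !grepl(.AXT_ALPHABET, is))
    msg <- c(msg, "sequences may contain only A,C,G,T,N,-")
  if (!object@infoStrand %in% c("+", "-"))
    msg <- c(msg, "infoStrand must be '+' or '-'")
  if (nchar(ts) == nchar(is) && nchar(ts) > 0L) {
    gap <- utf8ToInt("-")
    tg <- .seqCharCodes(ts) == gap
    ig <- .seqCharCodes(is) == gap
    if (any(tg & ig))
      msg <- c(msg, "columns gapped in both sequences are forbidden")
    if (object@targetEnd - object@targetStart + 1L != sum(!tg))
      msg <- c(msg, "target coordinate span must equal non-gap length of targetSeq")
    if (object@infoEnd - object@infoStart + 1L != sum(!ig))
      msg <- c(msg, "info coordinate span must equal non-gap length of infoSeq")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentPair
#'
#' Convenience constructor; `targetEnd`/`infoEnd` default to
#' `start + <non-gap length> - 1` when omitted.
#'
#' @param targetSeq,infoSeq equal-length gapped sequences (upper-cased on
#'   construction).
#' @param targetName,targetStart,targetEnd,infoName,infoStart,infoEnd,infoStrand,score
#'   metadata, see the class description.
#' @return an [AlignmentPair-class] object.
#' @examples
#' AlignmentPair("ACG-T", "ACGTT")
#' @export
AlignmentPair <- function(targetSeq, infoSeq,
                          targetName = "chrT", targetStart = 1L,
                          targetEnd = NA_integer_,
                          infoName = "chrI", infoStart = 1L,
                          infoEnd = NA_integer_,
                          infoStrand = "+", score = 0) {
  targetSeq <- toupper(targetSeq)
  infoSeq <- toupper(infoSeq)
  nongap <- function(s) nchar(gsub("-", "", s, fixed = TRUE))
  if (is.na(targetEnd))
    targetEnd <- as.integer(targetStart) + nongap(targetSeq) - 1L
  if (is.na(infoEnd))
    infoEnd <- as.integer(infoStart) + nongap(infoSeq) - 1L
  new("AlignmentPair",
      targetName = targetName, targetStart = as.integer(targetStart),
      targetEnd = as.integer(targetEnd),
      infoName = infoName, infoStart = as.integer(infoStart),
      infoEnd = as.integer(infoEnd),
      infoStrand = infoStrand, score = score,
      targetSeq = targetSeq, infoSeq = infoSeq)
}

#' TripletFrame: an alignment segmented into aligned triplet pairs
#'
#' One framing of an [AlignmentPair-class]: a strand and a frame offset
#' partition consecutive alignment columns into non-overlapping groups of
#' three.  Each group yields a target triplet code `h` and the aligned
#' information triplet code `m` over the 5-letter alphabet
#' `A=0, T=1, G=2, C=3, indel=4` (code `25*c1 + 5*c2 + c3`).
#'
#' @slot h,m integer triplet codes in `[0, 124]`, one per aligned triplet
#'   pair.
#' @slot strand `"+"` (alignment as given) or `"-"` (its reverse
#'   complement).
#' @slot offset number of leading columns skipped (0, 1 or 2).
#' @slot firstColumn,lastColumn first and last alignment column covered
#'   (1-based, on the strand-oriented alignment);
#'   `lastColumn - firstColumn + 1 == 3 * length(h)`.
#' @seealso [frameAlignment()], [encodeTriplet()]
#' @export
setClass("TripletFrame",
  representation(
    h = "integer", m = "integer",
    strand = "character", offset = "integer",
    firstColumn = "integer", lastColumn = "integer"
  ),
  prototype(h = integer(0), m = integer(0), strand = "+", offset = 0L,
            firstColumn = 1L, lastColumn = 0L)
)

setValidity("TripletFrame", function(object) {
  msg <- character(0)
  if (length(object@h) != length(object@m))
    msg <- c(msg, "h and m must have equal length")
  if (length(object@h) && (min(object@h, object@m) < 0L ||
                           max(object@h, object@m) > 124L))
    msg <- c(msg, "triplet codes must lie in [0, 124]")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (!object@offset %in% 0:2)
    msg <- c(msg, "offset must be 0, 1 or 2")
  if (object@lastColumn - object@firstColumn + 1L != 3L * length(object@h))
    msg <- c(msg, "column span must equal 3 * number of triplet pairs")
  if (length(msg)) msg else TRUE
})

#' CodonModel: codon and background conditional probability tables
#'
#' The four 125 x 125 row-stochastic tables of the log-odds model:
#' `PA[h', h]` is the probability of codon `h` given the previous codon
#' `h'`; `PB[h, m]` the probability of aligned information triplet `m`
#' given codon `h`; `QA`, `QB` are the analogous tables for noncoding
#' (background) triplets.  Rows are indexed by triplet code + 1.  Entries
#' are strictly positive (guaranteed by the estimation pseudocount).
#'
#' @slot PA,PB,QA,QB 125 x 125 row-stochastic matrices.
#' @slot pseudocount the pseudocount used in estimation (`NA` for
#'   hand-built models).
#' @seealso [estimateMatrices()], [lodSeries()], [writeCodonModel()]
#' @export
setClass("CodonModel",
  representation(PA = "matrix", PB = "matrix", QA = "matrix", QB = "matrix",
                 pseudocount = "numeric"),
  prototype(PA = matrix(1 / 125, 125, 125), PB = matrix(1 / 125, 125, 125),
            QA = matrix(1 / 125, 125, 125), QB = matrix(1 / 125, 125, 125),
            pseudocount = NA_real_)
)

setValidity("CodonModel", function(object) {
  msg <- character(0)
  for (nm in c("PA", "PB", "QA", "QB")) {
    mat <- slot(object, nm)
    if (!is.numeric(mat) || !identical(dim(mat), c(125L, 125L))) {
      msg <- c(msg, sprintf("%s must be a numeric 125 x 125 matrix", nm))
      next
    }
    if (any(!is.finite(mat)) || any(mat <= 0))
      msg <- c(msg, sprintf("%s must have strictly positive finite entries", nm))
    else if (max(abs(rowSums(mat) - 1)) > 1e-9)
      msg <- c(msg, sprintf("every row of %s must sum to 1 (within 1e-9)", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CodonModel-class
#' @param PA,PB,QA,QB row-stochastic 125 x 125 matrices.
#' @param pseudocount pseudocount recorded for provenance.
#' @return a `CodonModel` object.
#' @export
CodonModel <- function(PA, PB, QA, QB, pseudocount = NA_real_) {
  new("CodonModel", PA = PA, PB = PB, QA = QA, QB = QB,
      pseudocount = pseudocount)
}

#' ScoreSeries: log-odds values and their windowed averages
#'
#' The per-triplet log-odds series of one framed alignment (one value per
#' triplet pair after the first) and, once computed, the sliding-window
#' averages of width `w`.
#'
#' @slot lod numeric log-odds values (natural log), positions 2..L.
#' @slot windowed sliding means of `w` consecutive `lod` values (empty
#'   until computed).
#' @slot w window width in triplets (0 until `windowed` is filled).
#' @slot framing the [TripletFrame-class] that produced the series.
#' @seealso [lodSeries()], [windowedScores()]
#' @export
setClass("ScoreSeries",
  representation(lod = "numeric", windowed = "numeric", w = "integer",
                 framing = "TripletFrame"),
  prototype(lod = numeric(0), windowed = numeric(0), w = 0L)
)

setValidity("ScoreSeries", function(object) {
  if (length(object@windowed)) {
    if (object@w < 1L)
      return("w must be >= 1 when windowed scores are present")
    expected <- max(0L, length(object@lod) - object@w + 1L)
    if (length(object@windowed) != expected)
      return("length(windowed) must equal length(lod) - w + 1")
  }
  TRUE
})

#' NullCalibration: null-distribution parameters of the peak test
#'
#' The parameters entering the extreme-value p-value: `mu` is the mean of a
#' single null log-odds value, `sigma` the standard deviation of a windowed
#' mean score under the null (single-value SD divided by `sqrt(w)`), and
#' `p0` the probability that a noncoding alignment exhibits at least one
#' peak.  A calibration is tied to the window and smoothing parameters it
#' was estimated under.  Defaults are the reference human-mouse values
#' (`mu = -0.66`, `sigma = 0.527`, `p0 = 0.04` with `w0 = 20`, `w = 9`,
#' `f = span = 1/3`).
#'
#' @slot mu,sigma,p0 null parameters (see above); `sigma > 0`,
#'   `0 < p0 <= 1`.
#' @slot w,w0 window widths (triplets) for scoring and framing selection.
#' @slot f,span lowess fraction and peak-search span; `span == f` by
#'   convention.
#' @slot nAlignments number of null alignments behind the calibration
#'   (0 when the values are taken as given).
#' @seealso [calibrateNull()], [peakPValue()]
#' @export
setClass("NullCalibration",
  representation(mu = "numeric", sigma = "numeric", p0 = "numeric",
                 w = "integer", w0 = "integer", f = "numeric",
                 span = "numeric", nAlignments = "integer"),
  prototype(mu = -0.66, sigma = 0.527, p0 = 0.04, w = 9L, w0 = 20L,
            f = 1 / 3, span = 1 / 3, nAlignments = 0L)
)

setValidity("NullCalibration", function(object) {
  msg <- character(0)
  if (!is.finite(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be positive")
  if (!is.finite(object@p0) || object@p0 <= 0 || object@p0 > 1)
    msg <- c(msg, "p0 must lie in (0, 1]")
  if (!is.finite(object@f) || object@f <= 0 || object@f > 1)
    msg <- c(msg, "f must lie in (0, 1]")
  if (!is.finite(object@span) || object@span <= 0 || object@span > 1)
    msg <- c(msg, "span must lie in (0, 1]")
  if (object@w < 1L || object@w0 < 1L)
    msg <- c(msg, "w and w0 must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname NullCalibration-class
#' @param mu,sigma,p0,w,w0,f,span,nAlignments see the class slots.
#' @return a `NullCalibration` object.
#' @export
NullCalibration <- function(mu = -0.66, sigma = 0.527, p0 = 0.04,
                            w = 9L, w0 = 20L, f = 1 / 3, span = f,
                            nAlignments = 0L) {
  new("NullCalibration", mu = mu, sigma = sigma, p0 = p0,
      w = as.integer(w), w0 = as.integer(w0), f = f, span = span,
      nAlignments = as.integer(nAlignments))
}

#' AlignmentSimulator: ground-truth generating model for simulations
#'
#' A synthetic generating model for pairwise alignments: a first-order
#' Markov chain over the 125 triplet codes plus an emission table (target
#' triplet to aligned information triplet) for noncoding background, and a
#' tilted pair of tables for codon regions.  The coding tables are an
#' exponential tilt of the noncoding tables whose strength (`divergence`)
#' controls the expected per-codon log-odds signal; `divergence = 0` makes
#' the two models identical.
#'
#' @slot codingChain,codingEmission,noncodingChain,noncodingEmission
#'   125 x 125 row-stochastic matrices (zeros allowed: the emission gives
#'   zero mass to gap-on-gap columns).
#' @slot divergence the tilt strength actually used.
#' @slot seed the seed the tables were drawn from.
#' @seealso [sampleGroundTruth()], [simulateNullAlignment()],
#'   [expectedLod()]
#' @export
setClass("AlignmentSimulator",
  representation(codingChain = "matrix", codingEmission = "matrix",
                 noncodingChain = "matrix", noncodingEmission = "matrix",
                 divergence = "numeric", seed = "integer"),
  prototype(codingChain = matrix(1 / 125, 125, 125),
            codingEmission = matrix(1 / 125, 125, 125),
            noncodingChain = matrix(1 / 125, 125, 125),
            noncodingEmission = matrix(1 / 125, 125, 125),
            divergence = 0, seed = 0L)
)

setValidity("AlignmentSimulator", function(object) {
  msg <- character(0)
  for (nm in c("codingChain", "codingEmission", "noncodingChain",
               "noncodingEmission")) {
    mat <- slot(object, nm)
    if (!identical(dim(mat), c(125L, 125L))) {
      msg <- c(msg, sprintf("%s must be 125 x 125", nm))
      next
    }
    if (any(!is.finite(mat)) || any(mat < 0))
      msg <- c(msg, sprintf("%s must be non-negative and finite", nm))
    else if (max(abs(rowSums(mat) - 1)) > 1e-8)
      msg <- c(msg, sprintf("rows of %s must sum to 1", nm))
  }
  if (!is.finite(object@divergence) || object@divergence < 0)
    msg <- c(msg, "divergence must be >= 0")
  if (length(msg)) msg else TRUE
})
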