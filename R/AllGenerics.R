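#' @include AllClasses.R
NULL

#' Accessors for AlignmentPair
#'
#' `targetSeq()` and `infoSeq()` return the gapped sequence strings;
#' `alignmentLength()` the number of alignment columns (gaps included).
#'
#' @param x an [AlignmentPair-class].
#' @return a character string, or an integer for `alignmentLength()`.
#' @examples
#' aln <- AlignmentPair("ACG-T", "ACGTT")
#' targetSeq(aln)
#' alignmentLength(aln)
#' @export
setGeneric("targetSeq", function(x) standardGeneric("targetSeq"))

#' @rdname targetSeq
#' @export
setGeneric("infoSeq", function(x) standardGeneric("infoSeq"))

#' @rdname targetSeq
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname targetSeq
#' @export
setMethod("targetSeq", "AlignmentPair", function(x) x@targetSeq)

#' @rdname targetSeq
#' @export
setMethod("infoSeq", "AlignmentPair", function(x) x@infoSeq)

#' @rdname targetSeq
#' @export
setMethod("alignmentLength", "AlignmentPair",
          function(x) nchar(x@targetSeq))

#' Model matrices of a CodonModel
#'
#' @param x a [CodonModel-class].
#' @return a named list with elements `PA`, `PB`, `QA`, `QB`.
#' @export
setGeneric("modelMatrices", function(x) standardGeneric("modelMatrices"))

#' @rdname modelMatrices
#' @export
setMethod("modelMatrices", "CodonModel",
          function(x) list(PA = x@PA, PB = x@PB, QA = x@QA, QB = x@QB))

setMethod("show", "AlignmentPair", function(object) {
  n <- nchar(object@targetSeq)
  trunc <- function(s) if (nchar(s) > 50) paste0(substr(s, 1, 50), "...") else s
  cat(sprintf("AlignmentPair of %d columns\n", n))
  cat(sprintf("  target: %s:%d-%d\n", object@targetName, object@targetStart,
              object@targetEnd))
  cat(sprintf("  info:   %s:%d-%d (%s), score %g\n", object@infoName,
              object@infoStart, object@infoEnd, object@infoStrand,
              object@score))
  cat(sprintf("  T: %s\n  I: %s\n", trunc(object@targetSeq),
              trunc(object@infoSeq)))
})

setMethod("show", "TripletFrame", function(object) {
  cat(sprintf(
    "TripletFrame: %d aligned triplet pairs (strand %s, offset %d, columns %d-%d)\n",
    length(object@h), object@strand, object@offset, object@firstColumn,
    object@lastColumn))
})

setMethod("show", "CodonModel", function(object) {
  cat("CodonModel: four 125 x 125 row-stochastic tables (PA, PB, QA, QB)\n")
  cat(sprintf("  pseudocount: %s\n",
              ifelse(is.na(object@pseudocount), "unknown",
                     format(object@pseudocount))))
})

setMethod("show", "ScoreSeries", function(object) {
  cat(sprintf("ScoreSeries: %d log-odds values", length(object@lod)))
  if (length(object@windowed))
    cat(sprintf(", %d windowed scores (w = %d)", length(object@windowed),
                object@w))
  cat("\n")
})

setMethod("show", "NullCalibration", function(object) {
  cat("NullCalibration\n")
  cat(sprintf("  mu = %.4g, sigma = %.4g, p0 = %.4g\n", object@mu,
              object@sigma, object@p0))
  cat(sprintf("  w = %d, w0 = %d, f = %.4g, span = %.4g (from %d alignments)\n",
              object@w, object@w0, object@f, object@span,
              object@nAlignments))
})

setMethod("show", "AlignmentSimulator", function(object) {
  cat(sprintf(
    "AlignmentSimulator (seed %d): divergence %.4g between coding and background\n",
    object@seed, object@divergence))
})
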