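#' @include AllClasses.R AllGenerics.R utils.R codon-model.R
NULL

# log-tables cached per model to avoid re-taking logs in tight loops
.logTables <- function(model) {
  list(lPA = log(model@PA), lPB = log(model@PB),
       lQA = log(model@QA), lQB = log(model@QB))
}

# LOD_i = ln PA(h_i|h_{i-1}) + ln PB(m_i|h_i) - ln QA(.) - ln QB(.), i = 2..L
.lodFromCodes <- function(h, m, lt) {
  L <- length(h)
  prev <- h[-L] + 1L
  cur <- h[-1L] + 1L
  mcur <- m[-1L] + 1L
  lt$lPA[cbind(prev, cur)] + lt$lPB[cbind(cur, mcur)] -
    lt$lQA[cbind(prev, cur)] - lt$lQB[cbind(cur, mcur)]
}

#' Log-odds ratio series of a framed alignment
#'
#' For each aligned triplet pair after the first, the natural-log odds of
#' the codon model against the background model:
#' `LOD_i = ln PA(h_i | h_{i-1}) + ln PB(m_i | h_i) - ln QA(h_i | h_{i-1})
#' - ln QB(m_i | h_i)`, for `i = 2..L`.  All values are finite because the
#' model tables are strictly positive.
#'
#' @param frame a [TripletFrame-class] with at least 2 triplet pairs.
#' @param model a [CodonModel-class].
#' @return a [ScoreSeries-class] holding the `L - 1` log-odds values.
#' @seealso [windowedScores()], [selectFraming()]
#' @export
lodSeries <- function(frame, model) {
  if (length(frame@h) < 2L)
    stop("log-odds scoring needs at least 2 triplet pairs", call. = FALSE)
  lod <- .lodFromCodes(frame@h, frame@m, .logTables(model))
  new("ScoreSeries", lod = lod, windowed = numeric(0), w = 0L,
      framing = frame)
}

#' Sliding-window average scores
#'
#' Arithmetic means of `w` consecutive log-odds values with stride 1
#' (`S[i] = mean(lod[i..i+w-1])`); empty when fewer than `w` values are
#' available.
#'
#' @param lod numeric log-odds values (or a [ScoreSeries-class], whose
#'   `lod` slot is used).
#' @param w window width in triplets, `>= 1`.
#' @return numeric vector of `length(lod) - w + 1` windowed scores.
#' @examples
#' windowedScores(c(1, 2, 3, 4), w = 2) # 1.5 2.5 3.5
#' @export
windowedScores <- function(lod, w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 1)
    stop("window width w must be >= 1", call. = FALSE)
  if (is(lod, "ScoreSeries")) lod <- lod@lod
  .movingAverage(lod, as.integer(w))
}

#' Select the best framing of an alignment
#'
#' Enumerates all six framings (two strands times three frame offsets),
#' computes the log-odds series of each and the block averages
#' `S[i, w0]` over `w0` consecutive values, and returns the framing whose
#' block average is globally maximal, extended over the whole alignment in
#' triplet units (partial triplets dropped).  Ties are broken in favour of
#' the forward strand, then the smaller offset, then the leftmost block.
#'
#' @param aln an [AlignmentPair-class]; every framing must yield at least
#'   `w0 + 1` triplet pairs, i.e. at least `3 * (w0 + 1) + 2` columns.
#' @param model a [CodonModel-class].
#' @param w0 framing-selection window width in triplets (default 20).
#' @return a list with elements `framing` (the winning
#'   [TripletFrame-class]), `blockStart` (index of the maximal block in
#'   triplet-pair units within that framing's score series) and `lod`
#'   (the framing's log-odds values).
#' @param .lt precomputed log tables (internal fast path for batch
#'   callers; leave `NULL`).
#' @seealso [lodSeries()], [testCodingPotential()]
#' @export
selectFraming <- function(aln, model, w0 = 20L, .lt = NULL) {
  w0 <- as.integer(w0)
  stopifnot(w0 >= 1L)
  lt <- if (is.null(.lt)) .logTables(model) else .lt
  if (alignmentLength(aln) < 3L * (w0 + 1L) + 2L)
    stop(sprintf(
      "alignment too short for framing selection: %d columns, need at least %d (w0 = %d)",
      alignmentLength(aln), 3L * (w0 + 1L) + 2L, w0), call. = FALSE)
  dF_t <- .encodeSeq(aln@targetSeq)
  dF_i <- .encodeSeq(aln@infoSeq)
  dR_t <- rev(.COMPDIGIT[dF_t + 1L])
  dR_i <- rev(.COMPDIGIT[dF_i + 1L])
  best <- NULL
  for (strand in c("+", "-")) {
    dt <- if (strand == "+") dF_t else dR_t
    di <- if (strand == "+") dF_i else dR_i
    for (offset in 0:2) {
      h <- .digitsToCodes(dt, offset)
      if (length(h) < w0 + 1L) next
      m <- .digitsToCodes(di, offset)
      lod <- .lodFromCodes(h, m, lt)
      s0 <- .movingAverage(lod, w0)
      i <- which.max(s0)
      if (is.null(best) || s0[i] > best$score) {
        best <- list(score = s0[i], strand = strand, offset = offset,
                     h = h, m = m, lod = lod, blockStart = i)
      }
    }
  }
  framing <- new("TripletFrame", h = best$h, m = best$m,
                 strand = best$strand, offset = as.integer(best$offset),
                 firstColumn = as.integer(best$offset + 1L),
                 lastColumn = as.integer(best$offset + 3L * length(best$h)))
  list(framing = framing, blockStart = best$blockStart, lod = best$lod)
}
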