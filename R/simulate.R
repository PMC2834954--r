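#' @include AllClasses.R AllGenerics.R utils.R codon-model.R lod-scoring.R peak-test.R
NULL

# stationary distribution of a 125-state chain (principal left eigenvector)
.stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Draw a synthetic ground-truth generating model
#'
#' Builds the noncoding background first: chain rows are a symbol-level
#' triplet prior (independent symbols with a small indel rate) perturbed
#' by log-normal noise, and emission rows favour conservation — the
#' aligned triplet matches the target triplet symbol-by-symbol with high
#' probability, never aligning gap to gap.  The codon model is then an
#' exponential tilt of the background (`coding ∝ background * exp(knob *
#' G)` with a fixed Gaussian tilt direction `G`), renormalized row-wise,
#' so `divergence = 0` reproduces the background exactly and larger knobs
#' increase the expected per-codon log-odds signal monotonically.
#'
#' When `divergence` is `NULL` (the default) the knob is tuned by root
#' finding so that the exactly enumerated expected per-codon log-odds
#' under the codon model equals `targetLod` (1 nat by default), making
#' the signal strength seed-independent.
#'
#' @param seed integer seed; the same seed always yields the same tables.
#' @param divergence tilt strength `>= 0`, or `NULL` to tune it to
#'   `targetLod`.
#' @param targetLod expected per-codon log-odds (nats) to tune to.
#' @param gapRate per-symbol indel probability of the background prior.
#' @param matchProb probability that an aligned symbol matches the target
#'   symbol (conservation strength).
#' @param gapAlignProb probability that a target base aligns to a gap.
#' @param chainNoise,emissionNoise log-normal noise scales of the
#'   background rows.
#' @return an [AlignmentSimulator-class].
#' @examples
#' sim <- sampleGroundTruth(seed = 1, divergence = 0)
#' identical(sim@codingChain, sim@noncodingChain)
#' @importFrom stats rnorm uniroot
#' @export
sampleGroundTruth <- function(seed, divergence = NULL, targetLod = 1,
                              gapRate = 0.04, matchProb = 0.7,
                              gapAlignProb = 0.03, chainNoise = 0.3,
                              emissionNoise = 0.15) {
  if (!is.null(divergence) && (!is.finite(divergence) || divergence < 0))
    stop("divergence must be >= 0", call. = FALSE)
  draws <- .withSeed(seed, list(
    ZA = matrix(stats::rnorm(15625L), 125L),
    ZB = matrix(stats::rnorm(15625L), 125L),
    GA = matrix(stats::rnorm(15625L), 125L),
    GB = matrix(stats::rnorm(15625L), 125L)))
  psym <- c(rep((1 - gapRate) / 4, 4L), gapRate)
  priorTrip <- psym[.DIGITS[, 1L] + 1L] * psym[.DIGITS[, 2L] + 1L] *
    psym[.DIGITS[, 3L] + 1L]
  W <- matrix(priorTrip, 125L, 125L, byrow = TRUE) *
    exp(chainNoise * draws$ZA)
  ncChain <- W / rowSums(W)
  # per-symbol alignment emission; a target gap never aligns to a gap
  mis <- (1 - matchProb - gapAlignProb) / 3
  S5 <- matrix(mis, 5L, 5L)
  diag(S5) <- matchProb
  S5[, 5L] <- gapAlignProb
  S5[5L, ] <- c(rep(0.25, 4L), 0)
  M0 <- S5[.DIGITS[, 1L] + 1L, .DIGITS[, 1L] + 1L] *
    S5[.DIGITS[, 2L] + 1L, .DIGITS[, 2L] + 1L] *
    S5[.DIGITS[, 3L] + 1L, .DIGITS[, 3L] + 1L]
  E <- M0 * exp(emissionNoise * draws$ZB)
  ncEmis <- E / rowSums(E)
  tilt <- function(knob) {
    if (knob == 0) { # zero tilt reproduces the background exactly
      cc <- ncChain
      ce <- ncEmis
    } else {
      cc <- ncChain * exp(knob * draws$GA)
      cc <- cc / rowSums(cc)
      ce <- ncEmis * exp(knob * draws$GB)
      ce <- ce / rowSums(ce)
    }
    new("AlignmentSimulator",
        codingChain = cc, codingEmission = ce,
        noncodingChain = ncChain, noncodingEmission = ncEmis,
        divergence = knob, seed = as.integer(seed))
  }
  if (is.null(divergence)) {
    divergence <- stats::uniroot(
      function(k) expectedLod(tilt(k), under = "coding") - targetLod,
      interval = c(0, 4), tol = 1e-5, extendInt = "upX")$root
  }
  tilt(divergence)
}

#' Exactly enumerated expected log-odds per triplet pair
#'
#' The expectation of a single log-odds value over all `(h', h, m)`
#' triples, weighting `h'` by the stationary distribution of the chosen
#' chain, `h` by its transition row and `m` by its emission row.  By
#' default the log-odds ratio is the ground truth's own
#' (coding vs background); passing `model` instead evaluates an estimated
#' [CodonModel-class] as the scoring function, e.g. to predict the null
#' mean `mu` of a calibration.
#'
#' @param sim an [AlignmentSimulator-class].
#' @param under which generating model the expectation is taken under.
#' @param model optional [CodonModel-class] scoring tables; `NULL` uses
#'   the ground-truth ratio (cells outside the shared support contribute
#'   zero).
#' @return the expected log-odds in nats.
#' @export
expectedLod <- function(sim, under = c("coding", "noncoding"),
                        model = NULL) {
  under <- match.arg(under)
  chainU <- if (under == "coding") sim@codingChain else sim@noncodingChain
  emisU <- if (under == "coding") sim@codingEmission else
    sim@noncodingEmission
  if (is.null(model)) {
    posA <- sim@codingChain > 0 & sim@noncodingChain > 0
    RA <- matrix(0, 125L, 125L)
    RA[posA] <- log(sim@codingChain[posA] / sim@noncodingChain[posA])
    posB <- sim@codingEmission > 0 & sim@noncodingEmission > 0
    RB <- matrix(0, 125L, 125L)
    RB[posB] <- log(sim@codingEmission[posB] / sim@noncodingEmission[posB])
  } else {
    RA <- log(model@PA) - log(model@QA)
    RB <- log(model@PB) - log(model@QB)
  }
  pi0 <- .stationary(chainU)
  termA <- (chainU * pi0) * RA
  termB <- (emisU * pi0) * RB
  sum(termA[chainU > 0]) + sum(termB[emisU > 0])
}

# Markov-chain triplet codes for a batch of alignments (ragged lengths).
# Row i holds nTrips[i] codes; the chain starts from its stationary
# distribution, and sampling is grouped by current state so the number of
# sample.int() calls stays small.
.simChainBatch <- function(chain, nTrips, start = .stationary(chain)) {
  n <- length(nTrips)
  maxT <- max(nTrips)
  H <- matrix(NA_integer_, n, maxT)
  H[, 1L] <- sample.int(125L, n, replace = TRUE, prob = start) - 1L
  if (maxT >= 2L) for (t in 2:maxT) {
    act <- which(nTrips >= t)
    if (!length(act)) next
    prev <- H[act, t - 1L]
    newv <- integer(length(act))
    for (cc in unique(prev)) {
      sel <- prev == cc
      newv[sel] <- sample.int(125L, sum(sel), replace = TRUE,
                              prob = chain[cc + 1L, ]) - 1L
    }
    H[act, t] <- newv
  }
  H
}

# aligned information triplets given target triplets (grouped by code)
.emitBatch <- function(emission, H) {
  M <- H
  idx <- which(!is.na(H))
  hv <- H[idx]
  mv <- integer(length(idx))
  for (cc in unique(hv)) {
    sel <- hv == cc
    mv[sel] <- sample.int(125L, sum(sel), replace = TRUE,
                          prob = emission[cc + 1L, ]) - 1L
  }
  M[idx] <- mv
  M
}

# decode triplet codes into per-column symbol digits (3 x L matrix)
.codesToDigits <- function(codes) t(.DIGITS[codes + 1L, , drop = FALSE])

# resample the aligned triplet wherever a column would be gap-on-gap
.fixDoubleGaps <- function(hcodes, mcodes, emission) {
  for (iter in seq_len(1000L)) {
    tdig <- .codesToDigits(hcodes)
    idig <- .codesToDigits(mcodes)
    bad <- which(colSums(tdig == 4L & idig == 4L) > 0L)
    if (!length(bad)) return(mcodes)
    for (j in bad)
      mcodes[j] <- sample.int(125L, 1L, prob = emission[hcodes[j] + 1L, ]) - 1L
  }
  stop("could not resample gap-on-gap columns; emission puts too much mass on double gaps",
       call. = FALSE)
}

# build an AlignmentPair from triplet codes, truncating to lengthCols
.pairFromCodes <- function(hcodes, mcodes, lengthCols,
                           targetName = "simT", infoName = "simI") {
  tch <- .SYMCODES[as.vector(.codesToDigits(hcodes)) + 1L]
  ich <- .SYMCODES[as.vector(.codesToDigits(mcodes)) + 1L]
  keep <- seq_len(lengthCols)
  AlignmentPair(targetSeq = intToUtf8(tch[keep]),
                infoSeq = intToUtf8(ich[keep]),
                targetName = targetName, infoName = infoName)
}

.simulateNullImpl <- function(sim, lengths) {
  nTrips <- as.integer(ceiling(lengths / 3))
  H <- .simChainBatch(sim@noncodingChain, nTrips)
  M <- .emitBatch(sim@noncodingEmission, H)
  lapply(seq_along(lengths), function(i) {
    idx <- seq_len(nTrips[i])
    mc <- .fixDoubleGaps(H[i, idx], M[i, idx], sim@noncodingEmission)
    .pairFromCodes(H[i, idx], mc, lengths[i])
  })
}

#' Simulate a noncoding (null) alignment pair
#'
#' Target triplets follow the background Markov chain, started from its
#' stationary distribution so the null series is stationary; each aligned
#' information triplet is drawn from the background emission given the
#' target triplet.  Codes are decoded to characters
#' (digit 4 becomes `-`), columns that would be gapped in both sequences
#' are resampled, and the alignment is truncated to exactly `lengthCols`
#' columns.
#'
#' @param sim an [AlignmentSimulator-class].
#' @param lengthCols requested column count, `>= 3`.
#' @param seed integer seed (deterministic output).
#' @return an [AlignmentPair-class].
#' @seealso [sampleGroundTruth()], [simulateCodingAlignment()]
#' @export
simulateNullAlignment <- function(sim, lengthCols, seed) {
  if (!is.finite(lengthCols) || lengthCols < 3)
    stop("lengthCols must be >= 3", call. = FALSE)
  .withSeed(seed, .simulateNullImpl(sim, as.integer(lengthCols)))[[1L]]
}

.simulateCodingImpl <- function(sim, totalCols, codingFraction, strand,
                                offset) {
  offset <- as.integer(offset)
  usable <- totalCols - offset
  L <- usable %/% 3L
  rem <- usable - 3L * L
  if (L < 2L)
    stop("alignment too short for the requested coding geometry",
         call. = FALSE)
  nCoding <- max(1L, min(L, as.integer(round(codingFraction * totalCols / 3))))
  l0 <- (L - nCoding) %/% 2L + 1L
  l1 <- l0 + nCoding - 1L
  nFront <- as.integer(offset > 0L)
  nBack <- as.integer(rem > 0L)
  totT <- nFront + L + nBack
  # region flags per generated triplet (TRUE = codon model)
  coding <- logical(totT)
  coding[nFront + (l0:l1)] <- TRUE
  codes <- integer(totT)
  codes[1L] <- sample.int(125L, 1L,
                          prob = .stationary(sim@noncodingChain)) - 1L
  for (t in seq_len(totT)[-1L]) {
    chain <- if (coding[t]) sim@codingChain else sim@noncodingChain
    codes[t] <- sample.int(125L, 1L, prob = chain[codes[t - 1L] + 1L, ]) - 1L
  }
  mcodes <- integer(totT)
  for (t in seq_len(totT)) {
    emis <- if (coding[t]) sim@codingEmission else sim@noncodingEmission
    mcodes[t] <- sample.int(125L, 1L, prob = emis[codes[t] + 1L, ]) - 1L
    mcodes[t] <- .fixDoubleGaps(codes[t], mcodes[t], emis)
  }
  tch <- .SYMCODES[as.vector(.codesToDigits(codes)) + 1L]
  ich <- .SYMCODES[as.vector(.codesToDigits(mcodes)) + 1L]
  # keep the last `offset` columns of the front triplet and the first
  # `rem` columns of the back triplet so codons sit at the frame offset
  keep <- c(if (nFront) (3L - offset + 1L):3L else integer(0),
            nFront * 3L + seq_len(3L * L),
            if (nBack) nFront * 3L + 3L * L + seq_len(rem) else integer(0))
  aln <- AlignmentPair(targetSeq = intToUtf8(tch[keep]),
                       infoSeq = intToUtf8(ich[keep]),
                       targetName = "simT", infoName = "simI")
  if (strand == "-") aln <- reverseComplement(aln)
  list(alignment = aln, l0 = l0, l1 = l1, strand = strand,
       offset = offset, codingFraction = 3 * nCoding / totalCols)
}

#' Simulate an alignment with an embedded coding block
#'
#' A central block of codons drawn from the codon chain/emission is
#' flanked by background triplets, placed at the requested frame offset;
#' the whole alignment is reverse-complemented when `strand` is `"-"`.
#' The true codon block position is returned alongside the alignment.
#'
#' @param sim an [AlignmentSimulator-class].
#' @param totalCols total alignment columns.
#' @param codingFraction fraction of columns inside the codon block, in
#'   `(0, 1]` (default 0.43, the typical coding share of extended
#'   conserved coding alignments).
#' @param strand,offset planted framing of the codon block.
#' @param seed integer seed.
#' @return a list: `alignment` ([AlignmentPair-class]), `l0`, `l1` (first
#'   and last codon triplet index), `strand`, `offset`,
#'   `codingFraction` (realized).
#' @export
simulateCodingAlignment <- function(sim, totalCols, codingFraction = 0.43,
                                    strand = "+", offset = 0L, seed = 1L) {
  stopifnot(strand %in% c("+", "-"), offset %in% 0:2,
            codingFraction > 0, codingFraction <= 1)
  .withSeed(seed, .simulateCodingImpl(sim, as.integer(totalCols),
                                      codingFraction, strand, offset))
}

.sampleLengthImpl <- function(config, n) {
  fam <- config$family
  if (is.null(fam) || !fam %in% c("lognormal", "empirical"))
    stop("length distribution family must be 'lognormal' or 'empirical'",
         call. = FALSE)
  draw <- function(k) {
    if (fam == "lognormal") {
      if (!is.numeric(config$meanlog) || !is.numeric(config$sdlog))
        stop("lognormal length config needs numeric meanlog and sdlog",
             call. = FALSE)
      stats::rlnorm(k, config$meanlog, config$sdlog)
    } else {
      if (!length(config$values))
        stop("empirical length config needs a non-empty values vector",
             call. = FALSE)
      sample(as.numeric(config$values), k, replace = TRUE)
    }
  }
  x <- pmax(3L, as.integer(round(draw(n))))
  minCols <- config$min
  if (!is.null(minCols)) {
    for (iter in seq_len(10000L)) {
      short <- which(x <= minCols)
      if (!length(short)) break
      x[short] <- pmax(3L, as.integer(round(draw(length(short)))))
    }
    if (any(x <= minCols))
      stop("length distribution puts almost no mass above `min`",
           call. = FALSE)
  }
  x
}

#' Sample alignment lengths (columns)
#'
#' Draws positive integer column counts from a configured family: either
#' `list(family = "lognormal", meanlog, sdlog)` or
#' `list(family = "empirical", values)`.  An optional `min` entry
#' truncates the distribution to lengths strictly greater than `min`.
#' The default configuration ([defaultLengthConfig()]) is a log-normal
#' matched to conserved-alignment length quantiles (about 68% of draws
#' exceed 150 columns and 95% fall below roughly 600).
#'
#' @param config length-distribution configuration list.
#' @param n number of draws.
#' @param seed integer seed.
#' @return integer vector of column counts (minimum 3).
#' @export
sampleLength <- function(config = defaultLengthConfig(), n = 1L, seed = 1L) {
  .withSeed(seed, .sampleLengthImpl(config, n))
}

#' @rdname sampleLength
#' @param minCols optional strict lower bound carried into the config.
#' @export
defaultLengthConfig <- function(minCols = NULL) {
  list(family = "lognormal", meanlog = 5.32, sdlog = 0.65, min = minCols)
}

#' Simulate a labelled batch of alignments
#'
#' Convenience batch generator for benchmarking: `nNull` background
#' alignments with lengths from `lengthConfig`, plus `nCoding` alignments
#' with an embedded codon block, each with strand and frame offset drawn
#' uniformly.  Deterministic given `seed`.
#'
#' @param sim an [AlignmentSimulator-class].
#' @param nNull,nCoding how many alignments of each kind.
#' @param lengthConfig length configuration for the null alignments (see
#'   [sampleLength()]).
#' @param codingCols column count(s) for coding alignments (sampled with
#'   replacement when a vector).
#' @param codingFraction coding share of the coding alignments.
#' @param seed integer seed.
#' @return a list with `alignments` (list of [AlignmentPair-class], null
#'   first) and `annotations` (data frame: `id`, `type`, `l0`, `l1`,
#'   `strand`, `offset`).
#' @export
simulateAlignments <- function(sim, nNull = 0L, nCoding = 0L,
                               lengthConfig = defaultLengthConfig(),
                               codingCols = 450L, codingFraction = 0.43,
                               seed = 1L) {
  .withSeed(seed, {
    nulls <- if (nNull > 0L)
      .simulateNullImpl(sim, .sampleLengthImpl(lengthConfig, nNull))
    else list()
    codStrand <- sample(c("+", "-"), nCoding, replace = TRUE)
    codOffset <- sample(0:2, nCoding, replace = TRUE)
    codCols <- if (length(codingCols) > 1L)
      sample(as.integer(codingCols), nCoding, replace = TRUE)
    else rep(as.integer(codingCols), nCoding)
    cods <- lapply(seq_len(nCoding), function(i)
      .simulateCodingImpl(sim, codCols[i], codingFraction, codStrand[i],
                          codOffset[i]))
    n <- nNull + nCoding
    ann <- data.frame(
      id = sprintf("aln%d", seq_len(n)),
      type = rep(c("null", "coding"), c(nNull, nCoding)),
      l0 = c(rep(NA_integer_, nNull), vapply(cods, `[[`, integer(1), "l0")),
      l1 = c(rep(NA_integer_, nNull), vapply(cods, `[[`, integer(1), "l1")),
      strand = c(rep(NA_character_, nNull), codStrand),
      offset = c(rep(NA_integer_, nNull), codOffset),
      stringsAsFactors = FALSE)
    list(alignments = c(nulls, lapply(cods, `[[`, "alignment")),
         annotations = ann)
  })
}

#' Calibrate null parameters by simulation
#'
#' Simulates background alignments from the ground truth (or uses a
#' supplied list), scores them with the estimated model and derives the
#' [NullCalibration-class]: `mu` is the mean and `s` the standard
#' deviation of the pooled single log-odds values (scored in the fixed
#' forward frame, offset 0), `sigma = s / sqrt(w)`, and `p0` is the
#' fraction of alignments long enough to test that exhibit at least one
#' peak under the full framing-selection / windowing / lowess / peak
#' pipeline.  A zero peak fraction is floored at one over the number of
#' eligible alignments, with a warning.
#'
#' @param model the estimated [CodonModel-class] used for scoring.
#' @param sim an [AlignmentSimulator-class] (required unless `alignments`
#'   is given).
#' @param alignments optional pre-simulated null alignments (a list of
#'   [AlignmentPair-class]); at least 100.
#' @param n number of alignments to simulate when `alignments` is `NULL`
#'   (at least 100).
#' @param lengthConfig length distribution for simulated alignments.
#' @param w,w0,f,span scoring parameters the calibration is tied to.
#' @param seed integer seed.
#' @return a [NullCalibration-class].
#' @importFrom stats sd
#' @export
calibrateNull <- function(model, sim = NULL, alignments = NULL, n = 1000L,
                          lengthConfig = defaultLengthConfig(), w = 9L,
                          w0 = 20L, f = 1 / 3, span = f, seed = 1L) {
  w <- as.integer(w)
  w0 <- as.integer(w0)
  if (is.null(alignments)) {
    if (is.null(sim))
      stop("either `sim` or `alignments` must be supplied", call. = FALSE)
    if (n < 100L)
      stop("calibration needs at least 100 null alignments", call. = FALSE)
    alignments <- .withSeed(seed,
      .simulateNullImpl(sim, .sampleLengthImpl(lengthConfig, n)))
  } else if (length(alignments) < 100L) {
    stop("calibration needs at least 100 null alignments", call. = FALSE)
  }
  lt <- .logTables(model)
  lodAll <- unlist(lapply(alignments, function(a) {
    d <- .encodeSeq(a@targetSeq)
    if (length(d) < 6L) return(numeric(0))
    h <- .digitsToCodes(d, 0L)
    m <- .digitsToCodes(.encodeSeq(a@infoSeq), 0L)
    if (length(h) < 2L) return(numeric(0))
    .lodFromCodes(h, m, lt)
  }))
  if (!length(lodAll) || stats::sd(lodAll) == 0)
    stop("degenerate null log-odds values; cannot calibrate", call. = FALSE)
  mu <- mean(lodAll)
  sigma <- stats::sd(lodAll) / sqrt(w)
  minCols <- 3L * (w0 + 1L) + 2L
  eligible <- alignments[vapply(alignments, alignmentLength,
                                integer(1)) >= minCols]
  if (!length(eligible))
    stop("no alignment long enough to estimate p0", call. = FALSE)
  hasPeak <- vapply(eligible, function(a) {
    sel <- selectFraming(a, model, w0, .lt = lt)
    sw <- .movingAverage(sel$lod, w)
    if (length(sw) < 2L) return(FALSE)
    length(findPeaks(lowessSmooth(sw, f), span)) > 0L
  }, logical(1))
  p0 <- mean(hasPeak)
  if (p0 == 0) {
    warning("no peak observed in any null alignment; flooring p0 at 1/n")
    p0 <- 1 / length(eligible)
  }
  NullCalibration(mu = mu, sigma = sigma, p0 = p0, w = w, w0 = w0, f = f,
                  span = span, nAlignments = length(alignments))
}
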