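#' @include AllClasses.R AllGenerics.R utils.R alignment-io.R codon-model.R lod-scoring.R peak-test.R simulate.R
NULL

#' Run the full coding-potential test on one alignment
#'
#' Pipeline order: framing selection over both strands and all three
#' frame offsets (window `w0`), log-odds series, sliding window means
#' (width `w`), lowess smoothing (fraction `f`), peak selection (span),
#' peak statistic and extreme-value p-value.
#'
#' @param aln an [AlignmentPair-class].
#' @param model a [CodonModel-class].
#' @param calib a [NullCalibration-class] (also carries `w`, `w0`, `f`,
#'   `span`).
#' @return a list: `strand`, `offset`, `blockStart`, `sHat` (`NA` when no
#'   peak), `nScores`, `p`.
#' @seealso [scoreAlignments()]
#' @export
testCodingPotential <- function(aln, model, calib = NullCalibration()) {
  sel <- selectFraming(aln, model, calib@w0)
  sw <- .movingAverage(sel$lod, calib@w)
  nScores <- length(sw)
  if (nScores < 2L) {
    sHat <- NA_real_
    p <- 1
  } else {
    sm <- lowessSmooth(sw, calib@f)
    sHat <- testStatistic(sm, calib@span)
    p <- peakPValue(sHat, nScores, calib)
  }
  list(strand = sel$framing@strand, offset = sel$framing@offset,
       blockStart = sel$blockStart, sHat = sHat,
       nScores = max(nScores, 0L), p = p)
}

#' Score a batch of alignments
#'
#' Applies [testCodingPotential()] to every alignment longer than
#' `minLen` columns and adjusts the resulting p-values to q-values over
#' the tested batch.  Alignments failing the length filter (or too short
#' to frame) are reported with status `"skipped"` and excluded from the
#' q-value batch size `k`.
#'
#' @param alns list of [AlignmentPair-class] objects.
#' @param model a [CodonModel-class].
#' @param calib a [NullCalibration-class].
#' @param minLen column-count filter (strictly greater is kept).
#' @param ids optional character ids (default `aln1, aln2, ...`).
#' @return a data frame with one row per alignment: `id`, `targetName`,
#'   `targetStart`, `targetEnd`, `strand`, `offset`, `blockStart`,
#'   `sHat`, `nScores`, `p`, `q`, `status`.  Note that `q` depends on
#'   which other alignments are in the batch.
#' @export
scoreAlignments <- function(alns, model, calib = NullCalibration(),
                            minLen = 150L, ids = NULL) {
  n <- length(alns)
  if (is.null(ids)) ids <- sprintf("aln%d", seq_len(n))
  stopifnot(length(ids) == n)
  lt <- .logTables(model)
  res <- data.frame(
    id = ids,
    targetName = vapply(alns, function(a) a@targetName, character(1)),
    targetStart = vapply(alns, function(a) a@targetStart, integer(1)),
    targetEnd = vapply(alns, function(a) a@targetEnd, integer(1)),
    strand = NA_character_, offset = NA_integer_,
    blockStart = NA_integer_, sHat = NA_real_, nScores = NA_integer_,
    p = NA_real_, q = NA_real_, status = "skipped",
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (alignmentLength(alns[[i]]) <= minLen) next
    tr <- tryCatch({
      sel <- selectFraming(alns[[i]], model, calib@w0, .lt = lt)
      sw <- .movingAverage(sel$lod, calib@w)
      if (length(sw) < 2L) {
        list(strand = sel$framing@strand, offset = sel$framing@offset,
             blockStart = sel$blockStart, sHat = NA_real_,
             nScores = length(sw), p = 1)
      } else {
        sm <- lowessSmooth(sw, calib@f)
        sHat <- testStatistic(sm, calib@span)
        list(strand = sel$framing@strand, offset = sel$framing@offset,
             blockStart = sel$blockStart, sHat = sHat,
             nScores = length(sw),
             p = peakPValue(sHat, length(sw), calib))
      }
    }, error = function(e) NULL)
    if (is.null(tr)) next
    res$strand[i] <- tr$strand
    res$offset[i] <- tr$offset
    res$blockStart[i] <- tr$blockStart
    res$sHat[i] <- tr$sHat
    res$nScores[i] <- tr$nScores
    res$p[i] <- tr$p
    res$status[i] <- "tested"
  }
  tested <- res$status == "tested"
  if (any(tested)) res$q[tested] <- qValues(res$p[tested])
  res
}

#' Train a codon model from labelled alignments
#'
#' Frames each coding training alignment at its known codon framing
#' (strand and offset) and each noncoding alignment at the fixed forward
#' frame, then estimates the four probability tables with pseudocounts.
#' Alignments too short to frame are dropped with a message.
#'
#' @param codingAlignments,noncodingAlignments lists of
#'   [AlignmentPair-class] objects (either may be empty).
#' @param codingFramings optional data frame with `strand` and `offset`
#'   columns, one row per coding alignment (default: forward, offset 0).
#' @param pseudocount pseudocount for [estimateMatrices()].
#' @return a [CodonModel-class].
#' @export
trainCodonModel <- function(codingAlignments, noncodingAlignments,
                            codingFramings = NULL, pseudocount = 1) {
  nc <- length(codingAlignments)
  if (is.null(codingFramings))
    codingFramings <- data.frame(strand = rep("+", nc),
                                 offset = rep(0L, nc))
  stopifnot(nrow(codingFramings) == nc)
  frameSafe <- function(aln, strand, offset)
    tryCatch(frameAlignment(aln, strand, offset), error = function(e) NULL)
  cf <- Filter(Negate(is.null), lapply(seq_len(nc), function(i)
    frameSafe(codingAlignments[[i]], codingFramings$strand[i],
              as.integer(codingFramings$offset[i]))))
  nf <- Filter(Negate(is.null), lapply(noncodingAlignments, frameSafe,
                                       strand = "+", offset = 0L))
  dropped <- (nc - length(cf)) +
    (length(noncodingAlignments) - length(nf))
  if (dropped > 0L)
    .cpLog("info", "dropped %d training alignment(s) too short to frame",
           dropped)
  .cpLog("info", "training on %d coding and %d noncoding framed alignments",
         length(cf), length(nf))
  estimateMatrices(cf, nf, pseudocount)
}

#' Benchmark scored alignments against simulation ground truth
#'
#' Joins [scoreAlignments()] output with the annotations of
#' [simulateAlignments()] and reports, over tested alignments only: the
#' true positive rate (fraction of coding alignments with `p < alpha`),
#' the false positive rate (same fraction among null alignments) and the
#' planted strand/frame recovery rate of the coding alignments.  A
#' threshold `alpha >= 1` calls every alignment positive.
#'
#' @param results data frame from [scoreAlignments()].
#' @param annotations data frame with `id`, `type` (`"null"`/`"coding"`)
#'   and, for coding rows, planted `strand` and `offset`.
#' @param alpha p-value threshold (default 0.0387).
#' @return a list: `tp`, `fp`, `recovery` (each `NA` when its category is
#'   absent), `alpha`, `nCoding`, `nNull` (tested counts).
#' @export
benchmarkResults <- function(results, annotations, alpha = 0.0387) {
  if (!all(c("id", "type") %in% names(annotations)))
    stop("annotations must have 'id' and 'type' columns", call. = FALSE)
  m <- merge(results, annotations, by = "id", suffixes = c("", ".true"))
  m <- m[m$status == "tested", , drop = FALSE]
  called <- m$p < alpha | alpha >= 1
  isNull <- m$type == "null"
  isCoding <- m$type == "coding"
  recovery <- if (any(isCoding))
    mean(m$strand[isCoding] == m$strand.true[isCoding] &
           m$offset[isCoding] == m$offset.true[isCoding])
  else NA_real_
  list(tp = if (any(isCoding)) mean(called[isCoding]) else NA_real_,
       fp = if (any(isNull)) mean(called[isNull]) else NA_real_,
       recovery = recovery, alpha = alpha,
       nCoding = sum(isCoding), nNull = sum(isNull))
}

#' Serialize a NullCalibration as YAML
#'
#' @param calib a [NullCalibration-class].
#' @param file path to write to / read from.
#' @return `writeCalibration()` returns `file` invisibly;
#'   `readCalibration()` a [NullCalibration-class].
#' @export
writeCalibration <- function(calib, file) {
  yaml::write_yaml(list(mu = calib@mu, sigma = calib@sigma, p0 = calib@p0,
                        w = calib@w, w0 = calib@w0, f = calib@f,
                        span = calib@span,
                        n_alignments = calib@nAlignments), file)
  invisible(file)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(file) {
  x <- yaml::read_yaml(file)
  NullCalibration(mu = x$mu, sigma = x$sigma, p0 = x$p0, w = x$w,
                  w0 = x$w0, f = x$f, span = x$span,
                  nAlignments = x$n_alignments)
}

#' Pipeline configuration
#'
#' `defaultPipelineConfig()` returns the full default configuration:
#' scoring parameters (`w0 = 20`, `w = 9`, `f = span = 1/3`,
#' `pseudocount = 1`, `mu = -0.66`, `sigma = 0.527`, `p0 = 0.04`,
#' `alpha = 0.0387`, `q_threshold = 0.05`, `min_len = 150`), the
#' simulator block and file paths.  `readPipelineConfig()` reads a YAML
#' file and fills unset entries from the defaults.
#'
#' @param file YAML configuration path.
#' @return a nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    parameters = list(w0 = 20L, w = 9L, f = 1 / 3, span = 1 / 3,
                      pseudocount = 1, mu = -0.66, sigma = 0.527,
                      p0 = 0.04, alpha = 0.0387, q_threshold = 0.05,
                      min_len = 150L),
    simulator = list(divergence = NULL, target_lod = 1, n_null = 100L,
                     n_coding = 100L, coding_cols = 450L,
                     coding_fraction = 0.43,
                     lengths = defaultLengthConfig()),
    calibration = list(n = 1000L),
    paths = list(model = "model.txt", calibration = "calibration.yml",
                 input_axt = NULL, train_axt = NULL,
                 train_annotations = NULL, results_tsv = "results.tsv",
                 results_bed = "results.bed", sim_axt = "simulated.axt",
                 sim_annotations = "simulated_annotations.tsv",
                 metrics = "metrics.yml"),
    seed = 1L,
    log_level = "info")
}

#' @rdname defaultPipelineConfig
#' @export
readPipelineConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  def <- defaultPipelineConfig()
  for (block in names(def)) {
    if (is.list(def[[block]]) && !is.null(cfg[[block]]))
      def[[block]] <- utils::modifyList(def[[block]], cfg[[block]])
    else if (!is.null(cfg[[block]]))
      def[[block]] <- cfg[[block]]
  }
  def
}

.simFromConfig <- function(config) {
  sampleGroundTruth(seed = config$seed,
                    divergence = config$simulator$divergence,
                    targetLod = config$simulator$target_lod)
}

.applyLog <- function(config) {
  old <- options(CodingPotential.log = config$log_level)
  old
}

#' Pipeline commands
#'
#' File-based entry points behind the command-line interface; each reads
#' and writes the paths named in the configuration (see
#' [defaultPipelineConfig()]) and is deterministic given the configured
#' seed.
#'
#' * `cpSimulate()`: draws the ground truth, simulates `n_null` null and
#'   `n_coding` coding alignments and writes them as AXT plus a
#'   ground-truth annotation TSV.
#' * `cpTrain()`: reads training AXT + annotations, frames coding
#'   alignments at their annotated framing, estimates the model tables
#'   and writes the model file.
#' * `cpCalibrate()`: reads the model, simulates null alignments from the
#'   configured ground truth and writes the calibration YAML.
#' * `cpScore()`: reads model, calibration and input AXT, scores every
#'   alignment longer than `min_len` columns and writes the results TSV
#'   and the BED of calls with `q <= q_threshold`.
#' * `cpBenchmark()`: reads a results TSV and annotations and writes
#'   TP/FP/recovery metrics at the configured `alpha` as YAML.
#'
#' @param config configuration list (see [readPipelineConfig()]).
#' @return the main result of each step, invisibly (simulated batch,
#'   model, calibration, results data frame, metrics list).
#' @name pipelineCommands
NULL

#' @rdname pipelineCommands
#' @export
cpSimulate <- function(config = defaultPipelineConfig()) {
  old <- .applyLog(config); on.exit(options(old))
  sim <- .simFromConfig(config)
  s <- config$simulator
  out <- simulateAlignments(sim, nNull = s$n_null, nCoding = s$n_coding,
                            lengthConfig = s$lengths,
                            codingCols = s$coding_cols,
                            codingFraction = s$coding_fraction,
                            seed = config$seed + 1L)
  writeAxt(out$alignments, config$paths$sim_axt)
  utils::write.table(out$annotations, config$paths$sim_annotations,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .cpLog("info", "simulated %d null and %d coding alignments",
         s$n_null, s$n_coding)
  invisible(out)
}

#' @rdname pipelineCommands
#' @export
cpTrain <- function(config = defaultPipelineConfig()) {
  old <- .applyLog(config); on.exit(options(old))
  p <- config$paths
  if (is.null(p$train_axt) || !file.exists(p$train_axt))
    stop("config error: training AXT file not found", call. = FALSE)
  if (is.null(p$train_annotations) || !file.exists(p$train_annotations))
    stop("config error: training annotation file not found", call. = FALSE)
  alns <- readAxt(p$train_axt)
  ann <- utils::read.table(p$train_annotations, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(nrow(ann) == length(alns))
  isCoding <- ann$type == "coding"
  model <- trainCodonModel(
    alns[isCoding], alns[!isCoding],
    codingFramings = ann[isCoding, c("strand", "offset"), drop = FALSE],
    pseudocount = config$parameters$pseudocount)
  writeCodonModel(model, p$model)
  invisible(model)
}

#' @rdname pipelineCommands
#' @export
cpCalibrate <- function(config = defaultPipelineConfig()) {
  old <- .applyLog(config); on.exit(options(old))
  model <- readCodonModel(config$paths$model)
  pars <- config$parameters
  calib <- calibrateNull(model, sim = .simFromConfig(config),
                         n = config$calibration$n,
                         lengthConfig = config$simulator$lengths,
                         w = pars$w, w0 = pars$w0, f = pars$f,
                         span = pars$span, seed = config$seed + 2L)
  writeCalibration(calib, config$paths$calibration)
  .cpLog("info", "calibrated mu = %.4g, sigma = %.4g, p0 = %.4g",
         calib@mu, calib@sigma, calib@p0)
  invisible(calib)
}

#' @rdname pipelineCommands
#' @export
cpScore <- function(config = defaultPipelineConfig()) {
  old <- .applyLog(config); on.exit(options(old))
  p <- config$paths
  pars <- config$parameters
  if (is.null(p$input_axt) || !file.exists(p$input_axt))
    stop("config error: input AXT file not found", call. = FALSE)
  model <- readCodonModel(p$model)
  calib <- if (!is.null(p$calibration) && file.exists(p$calibration))
    readCalibration(p$calibration)
  else
    NullCalibration(mu = pars$mu, sigma = pars$sigma, p0 = pars$p0,
                    w = pars$w, w0 = pars$w0, f = pars$f,
                    span = pars$span)
  if (calib@w != pars$w || calib@w0 != pars$w0)
    stop("config error: calibration was made for different window sizes",
         call. = FALSE)
  alns <- readAxt(p$input_axt)
  res <- scoreAlignments(alns, model, calib, minLen = pars$min_len)
  writeResults(res, p$results_tsv, p$results_bed,
               qThreshold = pars$q_threshold)
  .cpLog("info", "scored %d alignments (%d tested, %d skipped)",
         nrow(res), sum(res$status == "tested"),
         sum(res$status == "skipped"))
  invisible(res)
}

#' @rdname pipelineCommands
#' @export
cpBenchmark <- function(config = defaultPipelineConfig()) {
  old <- .applyLog(config); on.exit(options(old))
  p <- config$paths
  res <- utils::read.table(p$results_tsv, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ann <- utils::read.table(p$sim_annotations, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"type" %in% names(ann))
    stop("config error: annotations lack a 'type' column", call. = FALSE)
  metrics <- benchmarkResults(res, ann,
                              alpha = config$parameters$alpha)
  yaml::write_yaml(metrics, p$metrics)
  .cpLog("info", "benchmark: tp = %s, fp = %s, recovery = %s",
         format(metrics$tp), format(metrics$fp),
         format(metrics$recovery))
  invisible(metrics)
}
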