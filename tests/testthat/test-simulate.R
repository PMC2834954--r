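simFixed <- sampleGroundTruth(seed = 1) # tuned to 1 nat per codon

test_that("sampleGroundTruth is deterministic and anchored at zero divergence", {
  s0 <- sampleGroundTruth(seed = 3, divergence = 0)
  expect_identical(s0@codingChain, s0@noncodingChain)
  expect_identical(s0@codingEmission, s0@noncodingEmission)
  a <- sampleGroundTruth(seed = 3, divergence = 0.5)
  b <- sampleGroundTruth(seed = 3, divergence = 0.5)
  expect_identical(a@codingChain, b@codingChain)
  expect_identical(a@noncodingEmission, b@noncodingEmission)
  expect_error(sampleGroundTruth(seed = 1, divergence = -1), ">= 0")
  for (m in list(a@codingChain, a@codingEmission, a@noncodingChain,
                 a@noncodingEmission))
    expect_equal(rowSums(m), rep(1, 125), tolerance = 1e-9)
  # a target gap never emits an aligned gap at the same position:
  # e.g. h = "---" (code 124) gives zero mass to every m containing '-'
  d <- cbind(0:124 %/% 25, (0:124 %/% 5) %% 5, 0:124 %% 5)
  hasGap <- rowSums(d == 4) > 0
  expect_true(all(a@noncodingEmission[125, hasGap] == 0))
  expect_true(all(a@noncodingEmission[125, !hasGap] > 0))
})

test_that("expected per-codon LOD is nondecreasing in the divergence knob", {
  knobs <- c(0, 0.5, 1, 2)
  e <- vapply(knobs, function(k)
    expectedLod(sampleGroundTruth(seed = 3, divergence = k)), numeric(1))
  expect_equal(e[1], 0, tolerance = 1e-12)
  expect_true(all(diff(e) > 0))
  # the default tuning hits the 1-nat target
  expect_equal(expectedLod(simFixed), 1, tolerance = 1e-3)
})

test_that("simulateNullAlignment gives exact lengths, determinism and no double gaps", {
  a <- simulateNullAlignment(simFixed, 300, seed = 2)
  expect_equal(alignmentLength(a), 300L)
  expect_identical(simulateNullAlignment(simFixed, 300, seed = 2), a)
  expect_false(identical(simulateNullAlignment(simFixed, 300, seed = 3), a))
  expect_error(simulateNullAlignment(simFixed, 2, seed = 1), ">= 3")
  expect_true(validObject(a)) # includes the no-double-gap invariant
})

test_that("simulated adjacent-triplet frequencies match the generating chain", {
  # ~1e5 triplets from long null alignments; compare the empirical
  # conditional next-triplet distribution to the chain row for the most
  # common states, within Monte-Carlo error
  alns <- withr::with_seed(8, lapply(1:60, function(i)
    simulateNullAlignment(simFixed, 5001, seed = 8000 + i)))
  hs <- lapply(alns, function(a) frameAlignment(a)@h)
  prev <- unlist(lapply(hs, function(h) h[-length(h)]))
  nxt <- unlist(lapply(hs, function(h) h[-1]))
  top <- as.integer(names(sort(table(prev), decreasing = TRUE)))[1:3]
  for (st in top) {
    sel <- prev == st
    n <- sum(sel)
    phat <- tabulate(nxt[sel] + 1L, 125) / n
    p <- simFixed@noncodingChain[st + 1L, ]
    se <- sqrt(pmax(p * (1 - p), 1e-12) / n)
    # standardized deviations behave like z-scores; allow a generous cap
    expect_lt(max(abs(phat - p) / pmax(se, 1e-6)), 5)
  }
})

test_that("simulateCodingAlignment plants the annotated codon block", {
  full <- simulateCodingAlignment(simFixed, 300, codingFraction = 1,
                                  seed = 4)
  expect_equal(full$l0, 1L)
  expect_equal(full$l1, 100L)
  expect_equal(alignmentLength(full$alignment), 300L)
  cs <- simulateCodingAlignment(simFixed, 450, codingFraction = 0.43,
                                strand = "-", offset = 2L, seed = 5)
  expect_equal(cs$strand, "-")
  expect_equal(cs$offset, 2L)
  blockCols <- 3 * (cs$l1 - cs$l0 + 1)
  expect_lt(abs(blockCols / 450 - 0.43), 3 / 450 + 0.01)
  expect_equal(alignmentLength(cs$alignment), 450L)
})

test_that("mean LOD inside the planted block exceeds the outside mean", {
  sim <- sampleGroundTruth(seed = 6, divergence = 2)
  # score with pseudocount-smoothed ground truth so all entries are positive
  smooth <- function(m) (m + 1e-6) / rowSums(m + 1e-6)
  model <- CodonModel(PA = smooth(sim@codingChain),
                      PB = smooth(sim@codingEmission),
                      QA = smooth(sim@noncodingChain),
                      QB = smooth(sim@noncodingEmission))
  din <- dout <- numeric(0)
  for (k in 1:100) {
    cs <- simulateCodingAlignment(sim, 450, codingFraction = 0.43,
                                  seed = 600 + k)
    fr <- frameAlignment(cs$alignment)
    lod <- lodSeries(fr, model)@lod # positions 2..L
    pos <- 2:length(fr@h)
    inside <- pos >= cs$l0 & pos <= cs$l1
    din <- c(din, lod[inside])
    dout <- c(dout, lod[!inside])
  }
  expect_gt(mean(din), mean(dout))
})

test_that("sampleLength honours families, truncation and determinism", {
  emp <- sampleLength(list(family = "empirical", values = c(200, 300)),
                      n = 50, seed = 1)
  expect_true(all(emp %in% c(200L, 300L)))
  tiny <- sampleLength(list(family = "lognormal", meanlog = 5,
                            sdlog = 1e-6), n = 20, seed = 2)
  expect_true(all(tiny == round(exp(5))))
  expect_identical(sampleLength(defaultLengthConfig(), n = 10, seed = 3),
                   sampleLength(defaultLengthConfig(), n = 10, seed = 3))
  trunc <- sampleLength(defaultLengthConfig(150), n = 200, seed = 4)
  expect_true(all(trunc > 150))
  expect_error(sampleLength(list(family = "weibull"), n = 1, seed = 1),
               "family")
})

test_that("calibrateNull recovers the enumerated null mean and a valid p0", {
  trn <- simulateAlignments(simFixed, nNull = 400, seed = 9)
  ctr <- simulateAlignments(simFixed, nCoding = 100, codingFraction = 1,
                            codingCols = 300, seed = 10)
  model <- trainCodonModel(ctr$alignments, trn$alignments,
                           codingFramings = ctr$annotations[, c("strand",
                                                                "offset")])
  calib <- calibrateNull(model, simFixed, n = 400, seed = 11)
  exact <- expectedLod(simFixed, under = "noncoding", model = model)
  # pooled single-LOD mean vs exact enumeration, within Monte-Carlo error
  nLod <- 400 * 80 # rough count of pooled LOD values
  se <- calib@sigma * sqrt(9) / sqrt(nLod)
  expect_lt(abs(calib@mu - exact), 4 * se)
  expect_gt(calib@p0, 0)
  expect_lte(calib@p0, 1)
  expect_error(calibrateNull(model, simFixed, n = 50, seed = 1),
               "at least 100")
})

test_that("with identical models every LOD is zero and calibration degenerates", {
  s0 <- sampleGroundTruth(seed = 12, divergence = 0)
  aln <- simulateNullAlignment(s0, 300, seed = 13)
  ss <- lodSeries(frameAlignment(aln), handModel())
  expect_equal(ss@lod, rep(0, length(ss@lod)))
  expect_error(calibrateNull(handModel(), s0, n = 100, seed = 14),
               "degenerate")
})
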