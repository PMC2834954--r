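# fixture builders shared across test files

# random gapped alignment pair with no gap-on-gap columns, independent of
# the package's simulator
randomAlignmentPair <- function(ncols, seed,
                                probs = c(0.23, 0.23, 0.23, 0.23, 0.08)) {
  withr::with_seed(seed, {
    draw <- function() sample(c("A", "T", "G", "C", "-"), ncols,
                              replace = TRUE, prob = probs)
    t <- draw()
    i <- draw()
    both <- which(t == "-" & i == "-")
    while (length(both)) {
      i[both] <- sample(c("A", "T", "G", "C"), length(both), replace = TRUE)
      both <- which(t == "-" & i == "-")
    }
    AlignmentPair(paste(t, collapse = ""), paste(i, collapse = ""))
  })
}

# uniform model with a few hand-set rows; `cells` is a data.frame with
# columns table ("PA","PB","QA","QB"), row, col (0-based codes), value
handModel <- function(cells = NULL) {
  mats <- list(PA = matrix(1 / 125, 125, 125), PB = matrix(1 / 125, 125, 125),
               QA = matrix(1 / 125, 125, 125), QB = matrix(1 / 125, 125, 125))
  if (!is.null(cells)) {
    for (k in seq_len(nrow(cells))) {
      tb <- cells$table[k]
      r <- cells$row[k] + 1L
      mats[[tb]][r, ] <- (1 - cells$value[k]) / 124
      mats[[tb]][r, cells$col[k] + 1L] <- cells$value[k]
    }
  }
  CodonModel(PA = mats$PA, PB = mats$PB, QA = mats$QA, QB = mats$QB)
}

# small deterministic training frames for counting oracles
randomFrames <- function(nFrames, len, seed) {
  withr::with_seed(seed, lapply(seq_len(nFrames), function(i) {
    h <- sample(0:124, len, replace = TRUE)
    m <- sample(0:124, len, replace = TRUE)
    new("TripletFrame", h = as.integer(h), m = as.integer(m),
        strand = "+", offset = 0L, firstColumn = 1L,
        lastColumn = as.integer(3L * len))
  }))
}
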