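#' @include AllClasses.R
NULL

# 5-letter alphabet digits: A=0, T=1, G=2, C=3, indel=4 (N treated as indel)
.SYMBOLS <- c("A", "T", "G", "C", "-")
.SYMCODES <- utf8ToInt(paste(.SYMBOLS, collapse = ""))

# char-code -> digit lookup (NA for anything outside A,C,G,T,N,-)
.CHARLUT <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("T") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("C") + 1L] <- 3L
  lut[utf8ToInt("N") + 1L] <- 4L
  lut[utf8ToInt("-") + 1L] <- 4L
  lut
})

# digit -> complement digit (A<->T, G<->C, indel fixed)
.COMPDIGIT <- c(1L, 0L, 3L, 2L, 4L)

# triplet code -> its three digits, row code+1
.DIGITS <- cbind(0:124 %/% 25L, (0:124 %/% 5L) %% 5L, 0:124 %% 5L)

# encode a sequence string into per-column digits; error on unknown chars
.encodeSeq <- function(s) {
  v <- utf8ToInt(s)
  d <- .CHARLUT[pmin(v, 127L) + 1L]
  if (anyNA(d)) {
    bad <- unique(intToUtf8(v[is.na(d)], multiple = TRUE))
    stop("unknown sequence character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d
}

# group consecutive digits (after skipping `offset`) into triplet codes
.digitsToCodes <- function(d, offset) {
  n <- (length(d) - offset) %/% 3L
  if (n < 1L) return(integer(0))
  idx <- offset + seq_len(3L * n)
  mat <- matrix(d[idx], nrow = 3L)
  25L * mat[1L, ] + 5L * mat[2L, ] + mat[3L, ]
}

# run code with a private RNG stream; the caller's RNG state is untouched
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# sliding mean of width w, stride 1; empty when length(x) < w
.movingAverage <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  cs <- cumsum(x)
  (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
}

.logLevels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

.cpLog <- function(level, fmt, ..., threshold = getOption("CodingPotential.log", "info")) {
  if (.logLevels[[level]] >= .logLevels[[threshold]] &&
      threshold != "quiet")
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
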