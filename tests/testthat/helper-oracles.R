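# Independent reference implementations used only as test oracles.
# These deliberately re-derive everything from first principles, without
# calling the package's internals.

# Cleveland's robust locally weighted regression (lowess) on x = 1..n,
# written out literally: k-nearest neighbourhood on sorted x, tricube
# distance weights, weighted degree-1 least squares, three bisquare
# robustness iterations with a 6*median(|residual|) scale.
oracleLowess <- function(y, f, iter = 3L) {
  n <- length(y)
  x <- seq_len(n)
  ns <- max(2L, min(n, floor(f * n + 1e-7)))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in 0:iter) {
    for (i in seq_len(n)) {
      # nearest-ns window around i over sorted x
      lo <- i; hi <- i
      while (hi - lo + 1L < ns) {
        if (lo == 1L) hi <- hi + 1L
        else if (hi == n) lo <- lo - 1L
        else if (x[i] - x[lo - 1L] <= x[hi + 1L] - x[i]) lo <- lo - 1L
        else hi <- hi + 1L
      }
      idx <- lo:hi
      h <- max(x[i] - x[lo], x[hi] - x[i])
      r <- abs(x[idx] - x[i])
      w <- numeric(length(idx))
      inside <- r <= 0.999 * h
      w[inside & r > 0.001 * h] <-
        (1 - (r[inside & r > 0.001 * h] / h)^3)^3
      w[r <= 0.001 * h] <- 1
      w <- w * rw[idx]
      if (sum(w) <= 0) { fit[i] <- y[i]; next }
      w <- w / sum(w)
      xb <- sum(w * x[idx])
      denom <- sum(w * (x[idx] - xb)^2)
      if (denom > 1e-12 * (x[hi] - x[lo])^2) {
        b <- sum(w * (x[idx] - xb) * y[idx]) / denom
        a <- sum(w * y[idx]) - b * xb
        fit[i] <- a + b * x[i]
      } else {
        fit[i] <- sum(w * y[idx])
      }
    }
    if (it == iter) break
    res <- y - fit
    cmad <- 6 * median(abs(res))
    if (cmad < 1e-7 * mean(abs(res)) || cmad == 0) break
    u <- abs(res) / cmad
    rw <- ifelse(u < 0.001, 1, ifelse(u > 0.999, 0, (1 - u^2)^2))
  }
  fit
}

# literal peak definition: interior index, >= everything in the centred
# window of half-width floor(span*n/2), strictly above both neighbours,
# leftmost among equal-valued peaks within one window
oraclePeaks <- function(s, span) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  h <- floor(span * n / 2)
  out <- integer(0)
  for (j in 2:(n - 1L)) {
    ok <- s[j] > s[j - 1L] && s[j] > s[j + 1L]
    if (ok) {
      for (i in max(1L, j - h):min(n, j + h))
        if (s[i] > s[j]) { ok <- FALSE; break }
    }
    if (ok && length(out)) {
      for (k in out)
        if (j - k <= h && s[k] == s[j]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, j)
  }
  out
}

# independent digit encoding (A=0, T=1, G=2, C=3, N/- = 4)
oracleDigits <- function(s) {
  map <- c(A = 0L, T = 1L, G = 2L, C = 3L, N = 4L, `-` = 4L)
  unname(map[strsplit(s, "")[[1]]])
}

# independent framing + LOD series for one strand/offset
oracleFrameCodes <- function(tseq, iseq, offset) {
  dt <- oracleDigits(tseq)
  di <- oracleDigits(iseq)
  L <- (length(dt) - offset) %/% 3
  h <- integer(L); m <- integer(L)
  for (k in seq_len(L)) {
    cols <- offset + (3 * (k - 1) + 1):(3 * k)
    h[k] <- 25 * dt[cols[1]] + 5 * dt[cols[2]] + dt[cols[3]]
    m[k] <- 25 * di[cols[1]] + 5 * di[cols[2]] + di[cols[3]]
  }
  list(h = h, m = m)
}

oracleRevComp <- function(s) {
  comp <- c(A = "T", T = "A", G = "C", C = "G", N = "N", `-` = "-")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

oracleLod <- function(h, m, model) {
  PA <- model@PA; PB <- model@PB; QA <- model@QA; QB <- model@QB
  L <- length(h)
  vapply(2:L, function(i)
    log(PA[h[i - 1] + 1, h[i] + 1]) + log(PB[h[i] + 1, m[i] + 1]) -
    log(QA[h[i - 1] + 1, h[i] + 1]) - log(QB[h[i] + 1, m[i] + 1]),
    numeric(1))
}

# exhaustive framing enumeration: all 6 framings, w0-block means by
# direct mean() calls, ties broken forward strand / smaller offset /
# leftmost block
oracleSelectFraming <- function(aln, model, w0 = 20L) {
  best <- NULL
  for (strand in c("+", "-")) {
    tseq <- if (strand == "+") targetSeq(aln) else
      oracleRevComp(targetSeq(aln))
    iseq <- if (strand == "+") infoSeq(aln) else oracleRevComp(infoSeq(aln))
    for (offset in 0:2) {
      fr <- oracleFrameCodes(tseq, iseq, offset)
      if (length(fr$h) < w0 + 1) next
      lod <- oracleLod(fr$h, fr$m, model)
      nblk <- length(lod) - w0 + 1
      s0 <- vapply(seq_len(nblk), function(i) mean(lod[i:(i + w0 - 1)]),
                   numeric(1))
      i <- which.max(s0)
      if (is.null(best) || s0[i] > best$score)
        best <- list(score = s0[i], strand = strand, offset = offset,
                     blockStart = i, h = fr$h, m = fr$m)
    }
  }
  best
}

# brute-force count tally for matrix estimation
oracleEstimate <- function(codingFrames, noncodingFrames, e = 1) {
  tally <- function(frames, kind) {
    cnt <- matrix(0, 125, 125)
    for (fr in frames) {
      h <- fr@h; m <- fr@m
      if (kind == "A") {
        if (length(h) >= 2)
          for (i in 2:length(h))
            cnt[h[i - 1] + 1, h[i] + 1] <- cnt[h[i - 1] + 1, h[i] + 1] + 1
      } else {
        for (i in seq_along(h))
          cnt[h[i] + 1, m[i] + 1] <- cnt[h[i] + 1, m[i] + 1] + 1
      }
    }
    cnt
  }
  norm <- function(cnt) {
    out <- matrix(0, 125, 125)
    for (r in 1:125)
      out[r, ] <- (cnt[r, ] + e) / (sum(cnt[r, ]) + 125 * e)
    out
  }
  list(PA = norm(tally(codingFrames, "A")),
       PB = norm(tally(codingFrames, "B")),
       QA = norm(tally(noncodingFrames, "A")),
       QB = norm(tally(noncodingFrames, "B")))
}
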