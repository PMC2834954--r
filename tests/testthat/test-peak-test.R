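test_that("lowessSmooth is exact on constants and straight lines", {
  expect_equal(lowessSmooth(rep(3.2, 15)), rep(3.2, 15), tolerance = 1e-12)
  y <- 0.5 * (1:30) - 4
  expect_equal(lowessSmooth(y, f = 1 / 3), y, tolerance = 1e-9)
  expect_error(lowessSmooth(1), "at least 2")
  expect_error(lowessSmooth(1:10, f = 0), "f must lie")
  expect_error(lowessSmooth(1:10, f = 1.5), "f must lie")
})

test_that("lowessSmooth matches the frozen reference fixture", {
  # 20-point pseudorandom series; expected values were computed with an
  # independent from-scratch implementation of robust locally weighted
  # regression (tricube weights, degree-1 fits, 3 bisquare iterations)
  y <- c(1.162685, -0.585924, 1.785465, -1.332594, -0.446567, 0.569606,
         -2.889718, -0.869018, -0.461703, -0.555541, -0.020135, -0.150382,
         -0.628127, 1.323221, -1.521351, -0.437428, 0.970578, 0.028223,
         -0.085782, 0.389214)
  expected <- c(0.798513788154285, 0.147213508308864, -0.503537176530912,
                -0.84949800259751, -0.413967953239809, -0.394934920533331,
                -0.388450870839107, -0.518693442623981, -0.602668075859542,
                -0.385908733583514, -0.299303754216904, -0.32368846910093,
                -0.629305027733928, -0.751260549537416, -0.72766347728603,
                -0.539639766220914, -0.141635430512875, 0.0854983521180689,
                0.162961798452522, 0.230267775171353)
  expect_equal(lowessSmooth(y, f = 1 / 3), expected, tolerance = 1e-6)
})

test_that("lowessSmooth agrees with the oracle on fresh random series", {
  for (s in 1:5) {
    y <- withr::with_seed(400 + s, cumsum(rnorm(35)))
    expect_equal(lowessSmooth(y, f = 1 / 3), oracleLowess(y, 1 / 3),
                 tolerance = 1e-9)
  }
})

test_that("findPeaks implements the window-dominance definition", {
  expect_identical(findPeaks(1:10, 1 / 3), integer(0)) # monotone: no peak
  expect_identical(findPeaks(c(1, 2, 3, 2, 1), span = 1), 3L)
  expect_identical(findPeaks(c(3, 1), 1 / 3), integer(0))
  expect_error(findPeaks(c(1, 2, 1), span = 0), "span")
  # invariant to adding a constant
  s <- withr::with_seed(9, rnorm(50))
  expect_identical(findPeaks(s, 1 / 3), findPeaks(s + 100, 1 / 3))
})

test_that("findPeaks matches the brute-force oracle on random series", {
  for (k in 1:100) {
    n <- 5 + (k %% 60)
    s <- withr::with_seed(500 + k, {
      x <- rnorm(n)
      if (k %% 3 == 0) x <- round(x) # force ties
      x
    })
    span <- c(0.2, 1 / 3, 0.8)[1 + k %% 3]
    expect_identical(findPeaks(s, span), oraclePeaks(s, span))
  }
})

test_that("testStatistic is the largest peak or absent", {
  expect_true(is.na(testStatistic(1:10, 1 / 3)))
  expect_equal(testStatistic(c(1, 2, 3, 2, 1), span = 1), 3)
  two <- c(0, 0.4, 0, 0, 0, 0, 0, 0, 0, 0, 1.1, 0)
  expect_equal(testStatistic(two, span = 0.3), 1.1)
})

test_that("peakPValue follows the extreme-value formula", {
  calib <- NullCalibration() # mu -0.66, sigma 0.527, p0 0.04
  expect_equal(peakPValue(NA_real_, 66, calib), 1)
  # at sHat == mu the z-score is 0 and p = (1 - 0.5^66) * p0
  expect_equal(peakPValue(-0.66, 66, calib), (1 - 0.5^66) * 0.04,
               tolerance = 1e-15)
  # frozen high-precision evaluation of the formula at sHat = 1.199, 74 scores
  expect_equal(peakPValue(1.199, 74, calib), 0.000616103226581433,
               tolerance = 1e-9)
  expect_error(peakPValue(1, 0, calib), "nScores")
})

test_that("peakPValue is monotone in sHat and nScores and stays in [0,1]", {
  calib <- NullCalibration()
  # range where Phi(z)^n is representable (far below it, p saturates at p0)
  s <- seq(0.25, 3, by = 0.25)
  p <- peakPValue(s, 70, calib)
  expect_true(all(diff(p) < 0)) # strictly decreasing in the statistic
  expect_equal(peakPValue(-5, 70, calib), calib@p0) # saturation limit
  n <- c(10, 20, 50, 100, 400)
  pn <- vapply(n, function(k) peakPValue(1.0, k, calib), numeric(1))
  expect_true(all(diff(pn) > 0)) # longer alignments give larger p
  grid <- expand.grid(s = c(-5, 0, 5, NA), n = c(1, 10, 1000))
  pv <- peakPValue(grid$s, grid$n, calib)
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("qValues applies the rank formula literally", {
  expect_equal(qValues(0.03), 0.03)
  expect_equal(qValues(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(qValues(c(0.5, 1, 0.01)), c(min(3 * 0.5 / 2, 1), 1, 0.03))
  # ties are broken by input order with consecutive ranks
  expect_equal(qValues(c(0.02, 0.02)), c(0.04, 0.02))
  p <- withr::with_seed(11, runif(200))
  q <- qValues(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_error(qValues(c(0.5, 1.2)), "0, 1")
  expect_error(qValues(numeric(0)), "at least one")
})
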