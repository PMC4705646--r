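# Entropy and mutual-information estimators.

test_that("Shannon entropy anchors", {
  expect_equal(shannonEntropy(c(10)), 0)            # all mass in one cell
  expect_equal(shannonEntropy(rep(4, 256)), 8)      # uniform over 256 cells
  expect_equal(shannonEntropy(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(round(shannonEntropy(c(3, 1)), 4), 0.8113)
  expect_error(shannonEntropy(numeric(0)), "empty")
})

test_that("orientation histograms use the 45-degree cell layout", {
  pr <- genRotationPair(0, 3000, seed = 1)
  h <- orientationHistogram(pr[[1]])
  expect_equal(h@nCells, 256)      # 8 x 4 x 8
  expect_equal(h@n, 3000)
  hj <- orientationHistogram(pr[[1]], pr[[2]])
  expect_equal(hj@nCells, 256^2)
  expect_equal(sum(hj@counts), 3000)
  ## marginals of the joint equal the single-variable histogram
  xid <- floor(as.numeric(names(hj@counts)) / 256)
  marg <- tapply(hj@counts, xid, sum)
  expect_equal(sort(as.numeric(marg)), sort(as.numeric(h@counts)))
})

test_that("MI_norm hits its endpoints", {
  pr <- genRotationPair(0, 5000, seed = 2)
  X <- pr[[1]]
  expect_equal(as.numeric(miNorm(X, X)), 1)     # identical series
  ## a deterministic bin relabelling keeps MI_norm at 1
  Y <- new("EulerSeries",
           angles = cbind(((X@angles[, 1] + 180 + 90) %% 360) - 180,
                          X@angles[, 2], X@angles[, 3]),
           pair = X@pair, frames = X@frames, meta = list())
  expect_equal(as.numeric(miNorm(X, Y)), 1)
  ## independence: MI_norm small and decreasing with N (the plug-in
  ## estimator's positive finite-sample bias shrinks with N; the reported
  ## analytic first-order term accounts for most of what remains)
  ms <- lapply(c(1000, 10000, 100000), function(n) {
    p <- genRotationPair(0, n, seed = 3)
    miNorm(p[[1]], p[[2]])
  })
  vals <- vapply(ms, as.numeric, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 0.05)
  expect_lt(vals[3] - attr(ms[[3]], "biasNorm"), 0.02)
})

test_that("MI respects its information-theoretic bounds and symmetry", {
  pr <- genRotationPair(0.5, 8000, seed = 4)
  m <- miNorm(pr[[1]], pr[[2]])
  hx <- shannonEntropy(orientationHistogram(pr[[1]]))
  hy <- shannonEntropy(orientationHistogram(pr[[2]]))
  expect_gte(attr(m, "mi"), 0)
  expect_lte(attr(m, "mi"), min(hx, hy) + 1e-12)
  expect_true(as.numeric(m) >= 0 && as.numeric(m) <= 1)
  m2 <- miNorm(pr[[2]], pr[[1]])
  expect_equal(as.numeric(m), as.numeric(m2), tolerance = 1e-12)
  ## estimated MI is monotone in the generator's correlation parameter
  mis <- vapply(c(0, 0.5, 1), function(cc) {
    p <- genRotationPair(cc, 8000, seed = 6)
    as.numeric(miNorm(p[[1]], p[[2]]))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("merging bins never increases MI (data processing)", {
  for (cc in c(0.3, 0.7)) {
    pr <- genRotationPair(cc, 8000, seed = 9)
    fine <- attr(miNorm(pr[[1]], pr[[2]], binWidth = 45), "mi")
    coarse <- attr(miNorm(pr[[1]], pr[[2]], binWidth = 90), "mi")
    expect_lte(coarse, fine + 1e-9)
  }
})

test_that("degenerate joint distribution is defined as zero with warning", {
  one <- new("EulerSeries", angles = cbind(c(10, 10), c(20, 20), c(30, 30)),
             pair = c("A", "B"), frames = 1:2, meta = list())
  expect_warning(m <- miNorm(one, one), "single cell")
  expect_equal(as.numeric(m), 0)
})
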