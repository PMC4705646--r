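# Helix frames, Euler decomposition, fraction-of-space statistics.

test_that("helix frames align with construction and are equivariant", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  fr <- helixFrame(ch, "stem")
  expect_s4_class(fr, "HelixFrame")
  ## rotating the whole conformation rotates the frame axes by exactly R
  R <- randomRotation(11)
  rot <- ch@coords %*% t(R)
  fr2 <- helixFrame(ch, "stem", coords = rot)
  expect_lt(max(abs(fr2@axes - R %*% fr@axes)), 1e-9)
  ## 1-bp helices have no axis
  ss1 <- parseStructure("GAAAC", pairs = data.frame(i = 1, j = 5))
  ch1 <- buildChain(ss1, seed = 1, relax = FALSE)
  expect_error(helixFrame(ch1, "H1"), "1-bp")
})

test_that("axis from a sub-helix agrees with the full helix", {
  ff <- forceFieldParams()
  tpl <- buildAformHelix(11, ff)$coords
  sIdx <- 3 * seq_len(22) - 1
  full <- rnatopo:::.cppFitFrames(matrix(t(tpl[sIdx, ]), nrow = 1),
                                  tpl[sIdx, ], seq_len(22))
  ## first 6 bp: strand-1 sugars 1..6 and their partners (17..22)
  sub <- c(1:6, 17:22)
  subTpl <- buildAformHelix(6, ff)$coords[3 * seq_len(12) - 1, ]
  subFit <- rnatopo:::.cppFitFrames(matrix(t(tpl[sIdx[sub], ]), nrow = 1),
                                    subTpl, seq_len(12))
  zFull <- matrix(full$rot[1, ], 3, 3, byrow = TRUE)[, 3]
  zSub <- matrix(subFit$rot[1, ], 3, 3, byrow = TRUE)[, 3]
  angle <- acos(min(1, sum(zFull * zSub))) * 180 / pi
  expect_lt(angle, 1)
})

test_that("Euler decomposition matches its defining conventions", {
  I3 <- diag(3)
  expect_equal(unname(eulerAngles(I3, I3)), c(0, 0, 0))
  ## pure 90-degree bend about A's y-axis
  Ry90 <- recomposeEuler(0, 90, 0)
  a <- eulerAngles(I3, Ry90)
  expect_equal(unname(a), c(0, 90, 0))
  ## round-trip on random rotations to 1e-9
  worst <- 0
  for (k in 1:1000) {
    R <- randomRotation()
    e <- eulerAngles(I3, R)
    worst <- max(worst, max(abs(recomposeEuler(e[1], e[2], e[3]) - R)))
  }
  expect_lt(worst, 1e-9)
  ## inverse rotations: euler(A,B) and euler(B,A) recompose to transposes
  set.seed(31)
  A <- randomRotation(); B <- randomRotation()
  eab <- eulerAngles(A, B); eba <- eulerAngles(B, A)
  expect_lt(max(abs(recomposeEuler(eab[1], eab[2], eab[3]) -
                      t(recomposeEuler(eba[1], eba[2], eba[3])))), 1e-9)
})

test_that("angle ranges and gimbal handling follow the stated convention", {
  set.seed(7)
  for (k in 1:200) {
    e <- eulerAngles(diag(3), randomRotation())
    expect_true(e[1] >= -180 && e[1] < 180)
    expect_true(e[2] >= 0 && e[2] <= 180)
    expect_true(e[3] >= -180 && e[3] < 180)
  }
  ## gimbal: all twist assigned to alpha, gamma = 0
  g <- eulerAngles(diag(3), recomposeEuler(50, 0, 30))
  expect_equal(unname(g[3]), 0)
  expect_equal(unname(g[1]), 80)
})

test_that("fraction sampled counts occupied bins over the full grid", {
  one <- new("EulerSeries", angles = cbind(12.3, 45.6, -90.1),
             pair = c("A", "B"), frames = 1L, meta = list())
  expect_equal(fractionSampled(one, 10), 1 / 23328)

  ## a series visiting every bin centre exactly once covers the space
  centres <- expand.grid(a = seq(-175, 175, by = 10),
                         b = seq(5, 175, by = 10),
                         g = seq(-175, 175, by = 10))
  full <- new("EulerSeries", angles = as.matrix(centres),
              pair = c("A", "B"), frames = seq_len(nrow(centres)),
              meta = list())
  expect_equal(fractionSampled(full, 10), 1)

  expect_error(fractionSampled(one, 7), "divide")

  ## edge samples belong to the higher bin
  edge <- new("EulerSeries", angles = rbind(c(-180, 0, -180), c(-170, 0, -180)),
              pair = c("A", "B"), frames = 1:2, meta = list())
  expect_equal(fractionSampled(edge, 10) * 23328, 2)
  near <- new("EulerSeries",
              angles = rbind(c(-180, 0, -180), c(-170.001, 0, -180)),
              pair = c("A", "B"), frames = 1:2, meta = list())
  expect_equal(fractionSampled(near, 10) * 23328, 1)
})

test_that("occupancy matches a brute-force histogram on random rotations", {
  pr <- genRotationPair(0, 20000, seed = 5)
  es <- pr[[1]]
  f <- fractionSampled(es, 10)
  ## independent direct count
  a <- es@angles
  key <- paste(floor((a[, 1] + 180) / 10), pmin(floor(a[, 2] / 10), 17),
               floor((a[, 3] + 180) / 10))
  expect_equal(f, length(unique(key)) / 23328)
  ## sin(beta) weighting leaves polar bins rare: coverage stays below 1
  expect_lt(f, 1)
  expect_gt(f, 0.3)
})

test_that("joint fractions use the k-th power denominator", {
  pr <- genRotationPair(1, 500, seed = 8)   # identical series
  f1 <- fractionSampled(pr[[1]], 30)
  f2 <- fractionJoint(pr, 30)
  n1 <- 12 * 6 * 12
  ## perfectly correlated: joint occupied count equals the single count
  expect_equal(f2 * n1^2, f1 * n1)
  ## three perfectly correlated series at 60 degrees
  f3 <- fractionJoint(list(pr[[1]], pr[[1]], pr[[2]]), 60)
  n60 <- 6 * 3 * 6
  expect_equal(f3 * n60^3, fractionSampled(pr[[1]], 60) * n60)
  expect_equal(n1^2, 746496)
  expect_equal(n60^3, 1259712)
  ## misaligned series are rejected
  bad <- new("EulerSeries", angles = pr[[1]]@angles[1:10, ],
             pair = c("x", "y"), frames = 2:11, meta = list())
  expect_error(fractionJoint(list(pr[[1]], bad)), "aligned")
})

test_that("F_samp is monotonically non-decreasing in N", {
  pr <- genRotationPair(0, 5000, seed = 13)
  a <- pr[[1]]@angles
  fs <- vapply(c(500, 1000, 2500, 5000), function(n) {
    s <- new("EulerSeries", angles = a[seq_len(n), ], pair = c("A", "B"),
             frames = seq_len(n), meta = list())
    fractionSampled(s, 30)
  }, numeric(1))
  expect_true(all(diff(fs) >= 0))
})

test_that("normalized fraction subsampling matches the reference density", {
  pr <- genRotationPair(0.3, 6000, seed = 2)
  out <- fractionNorm(pr, fTrna = 0.5, seed = 4)
  expect_equal(out$nConf, 4621)   # ceiling(499000 * 108^2 / 108^3)
  expect_equal(out$fNorm, out$fStar / 0.5)
  ## F*_samp equal to the reference fraction normalizes to 1
  out2 <- fractionNorm(pr, fTrna = out$fStar, seed = 4)
  expect_equal(out2$fNorm, 1)
  ## pool smaller than the subsample is an error, as is a missing F_trna
  small <- lapply(pr, function(s)
    new("EulerSeries", angles = s@angles[1:100, ], pair = s@pair,
        frames = s@frames[1:100], meta = list()))
  expect_error(fractionNorm(small, fTrna = 0.5), "smaller")
  expect_error(fractionNorm(pr), "fTrna")
})
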