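# Energy function, Monte Carlo sampling, replica exchange, geometric
# observables.

test_that("energy terms behave at their anchors", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  e <- chainEnergy(ch)
  expect_equal(e[["noe"]], 0)          # no noncanonical pairs
  expect_equal(e[["attraction"]], 0)
  expect_lt(e[["ev"]], 10)             # relaxed: at most grazing contact
  expect_true(is.finite(e[["total"]]))
  ## the ideal duplex itself carries zero repulsion: no nonbonded pair of
  ## the rigid template is closer than the steric diameter
  tpl <- ch@templates[["stem"]]
  res <- rep(seq_len(6), each = 3)
  minD <- Inf
  for (i in seq_len(nrow(tpl) - 1)) for (j in (i + 1):nrow(tpl)) {
    if (abs(res[i] - res[j]) <= 1) next
    minD <- min(minD, sqrt(sum((tpl[i, ] - tpl[j, ])^2)))
  }
  expect_gt(minD, 2 * ffParam(ch@ff, "ev_S"))
  bad <- ch@coords; bad[1, 1] <- NaN
  expect_error(chainEnergy(ch, bad), "NaN")
})

test_that("the repulsive core dominates at close contact", {
  ss <- parseStructure("AAA", "...")
  ch <- buildChain(ss, seed = 1, relax = FALSE)
  x <- ch@coords
  x[3, ] <- x[7, ] + 0.1   # B(1) onto P(3): non-excluded pair
  e <- chainEnergy(ch, x)
  expect_gt(e[["ev"]], 10 * 0.6)  # >> kT at 300 K
})

test_that("flat-bottom restraints are zero inside and force-capped outside", {
  ss <- parseStructure("AAA", "...")
  ch <- buildChain(ss, seed = 1, relax = FALSE)
  mkr <- function() new("RestraintSet", kind = "custom",
    noe = data.frame(i = 2L, j = 8L, rmin = 6, rmax = 8, kmin = 2, kmax = 2,
                     fmax = 2),
    dihedral = rnatopo:::.emptyDih(), rg = list())
  place <- function(d) {
    x <- ch@coords
    x[8, ] <- x[2, ] + c(d, 0, 0)
    x
  }
  eAt <- function(d) {
    chainEnergy(ch, place(d), restraints = mkr())[["noe"]] -
      chainEnergy(ch, place(d))[["noe"]]
  }
  expect_equal(eAt(7), 0)                       # mid-window: exactly zero
  expect_equal(eAt(6), 0); expect_equal(eAt(8), 0)
  expect_equal(eAt(8.5), 0.5 * 2 * 0.5^2)       # harmonic branch
  ## past the force cap (fmax/k = 1 A): linear continuation
  expect_equal(eAt(10), 0.5 * 2 * 1^2 + 2 * (2 - 1))
  expect_equal(eAt(4), 0.5 * 2 * 1^2 + 2 * (2 - 1))  # symmetric low side
})

test_that("a harmonic dimer samples the Boltzmann distribution", {
  ss <- parseStructure("A", ".")
  ch <- buildChain(ss, seed = 1, relax = FALSE)
  cfg <- samplerConfig(temps = 300, exchangeEvery = 1000,
                       totalMoves = 800000, recordEvery = 10, seed = 5,
                       record = "all", equilFrac = 0.05)
  traj <- remdRun(ch, config = cfg)
  idx <- postEquilIdx(traj)
  rPS <- sqrt(rowSums((traj@frames[idx, 1, ] - traj@frames[idx, 2, ])^2))
  kB <- ffParam(ch@ff, "k_bond")
  RT <- 1.9872e-3 * 300
  ## variance of the bond length matches RT/k within 2%
  expect_lt(abs(var(rPS) / (RT / kB) - 1), 0.02)

  ## two-state detailed-balance check: occupancy of r < b0 vs r >= b0
  ## against the closed-form Boltzmann weights (with the r^2 Jacobian)
  b0 <- rnatopo:::aformReference(ch@ff)$b_PS
  dens <- function(r) r^2 * exp(-kB * (r - b0)^2 / (2 * RT))
  Z1 <- integrate(dens, 0, b0)$value
  Z2 <- integrate(dens, b0, b0 + 10)$value
  pBelow <- mean(rPS < b0)
  ## block standard error (correlation-aware)
  blocks <- tapply(rPS < b0, cut(seq_along(rPS), 40), mean)
  se <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(pBelow - Z1 / (Z1 + Z2)), 3 * se + 1e-3)
})

test_that("a free chain reproduces the freely-jointed closed form", {
  n <- 11
  ss <- parseStructure(strrep("U", n), strrep(".", n))
  ch <- buildChain(ss, seed = 1, relax = FALSE)
  cfg <- samplerConfig(temps = 300, exchangeEvery = 1000,
                       totalMoves = 400000, recordEvery = 50, seed = 9,
                       record = "all", equilFrac = 0.05, ev = FALSE,
                       angles = FALSE)
  traj <- remdRun(ch, config = cfg)
  idx <- postEquilIdx(traj)
  ## end-to-end over the backbone: P(1) to S(n)
  ree2 <- rowSums((traj@frames[idx, 3 * n - 1, ] - traj@frames[idx, 1, ])^2)
  b <- ch@terms$bonds
  bb <- b[b$j %% 3 != 0, ]  # backbone bonds only (drop S-B attachments)
  expected <- sum(bb$b0^2)
  blocks <- tapply(ree2, cut(seq_along(ree2), 30), mean)
  se <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(ree2) - expected), 3 * se + 0.02 * expected)
})

test_that("rigid helices never deform across a full run", {
  traj <- azTraj()
  hm <- traj@helices[["P3"]]
  rows <- hm$rows
  d12 <- sqrt(rowSums((traj@frames[, rows[1], ] -
                         traj@frames[, rows[length(rows)], ])^2))
  expect_lt(max(d12) - min(d12), 1e-6)
  ## and the observed spacing is the template spacing
  tplD <- sqrt(sum((hm$tplS[1, ] - hm$tplS[nrow(hm$tplS), ])^2))
  expect_lt(max(abs(d12 - tplD)), 1e-6)
})

test_that("sampling is reproducible under a fixed seed", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  cfg <- samplerConfig(temps = tempLadder(n = 3), exchangeEvery = 200,
                       totalMoves = 4000, recordEvery = 20, seed = 21)
  t1 <- remdRun(ch, config = cfg)
  t2 <- remdRun(ch, config = cfg)
  expect_identical(t1@frames, t2@frames)
  expect_identical(t1@exchange, t2@exchange)
})

test_that("replica exchange reduces to the expected limits", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  ## near-degenerate ladder: every exchange is accepted
  cfg <- samplerConfig(temps = c(300, 300 + 1e-9), exchangeEvery = 100,
                       totalMoves = 5000, recordEvery = 50, seed = 2)
  traj <- remdRun(ch, config = cfg)
  expect_equal(traj@exchange$rate, 1)
  ## single temperature: plain Metropolis, no exchange records
  cfg1 <- samplerConfig(temps = 300, exchangeEvery = 100, totalMoves = 2000,
                        recordEvery = 50, seed = 2)
  t1 <- remdRun(ch, config = cfg1)
  expect_equal(nrow(t1@exchange), 0)
})

test_that("radius of gyration and P-bead RMSD anchors hold", {
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radiusOfGyration(two), 3)
  expect_equal(radiusOfGyration(rbind(two[1, ], two[1, ])), 0)
  expect_error(radiusOfGyration(two[1, , drop = FALSE]), "two beads")

  set.seed(4)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabschRmsd(A, A), 0, tolerance = 1e-10)
  R <- randomRotation(7)
  B <- A %*% t(R) + matrix(c(3, -2, 5), 10, 3, byrow = TRUE)
  expect_lt(kabschRmsd(A, B), 1e-6)

  ## 3-point toy against an independent R-side Kabsch
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0), 3, 3, byrow = TRUE)
  Q <- matrix(c(0, 0, 0, 1.2, 0, 0, 0, 1.9, 0.3), 3, 3, byrow = TRUE)
  rmsdRef <- local({
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    s <- svd(t(Pc) %*% Qc)
    d <- sign(det(s$v %*% t(s$u)))
    num <- sum(Pc^2) + sum(Qc^2) - 2 * sum(s$d * c(1, 1, d))
    sqrt(max(0, num) / 3)
  })
  expect_equal(kabschRmsd(P, Q), rmsdRef, tolerance = 1e-10)
})

test_that("trajectory text serialization round-trips", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  cfg <- samplerConfig(temps = 300, exchangeEvery = 100, totalMoves = 1000,
                       recordEvery = 100, seed = 3)
  traj <- remdRun(ch, config = cfg)
  f <- tempfile(fileext = ".tsv")
  writeTrajectoryTSV(traj, f)
  back <- readTrajectoryTSV(f)
  expect_equal(back$frames, unname(traj@frames), tolerance = 1e-4)
  expect_equal(back$seed, 3L)
  expect_equal(back$selection, traj@selection)
})
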