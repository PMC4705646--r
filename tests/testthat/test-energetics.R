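# Contact probabilities and the free-energy stack.

test_that("dG_topo evaluates its closed form and antisymmetry", {
  expect_equal(dgTopo(0.5), 0)
  expect_equal(round(dgTopo(0.003, 300), 2), 3.46)
  for (p in c(0.1, 0.25, 0.4))
    expect_equal(dgTopo(p), -dgTopo(1 - p), tolerance = 1e-12)
  expect_error(dgTopo(0), "strictly inside")
  expect_error(dgTopo(1), "strictly inside")
})

test_that("ddG_coop and dG_fold are the stated arithmetic", {
  expect_equal(ddgCoop(2.0, 2.0), 0)
  expect_equal(ddgCoop(2.4, 4.3), -1.9)
  expect_error(ddgCoop(Inf, 1), "finite")

  fp <- foldEnergyParams(-0.3, 2.9)
  expect_equal(dgFold(3.5, fp), 0.3)
  expect_equal(dgFold(2.9, fp), -0.3)        # identity at the reference
  d <- runif(1, -2, 2)
  expect_equal(dgFold(1 + d, fp) - dgFold(1, fp), d)  # linearity
})

test_that("contact probability recovers generator ground truth exactly", {
  g <- genContactEnsemble(0.25, 100000, seed = 5)
  fe <- contactProbability(g$traj, g$cdef, seed = 1)
  ## empirical frequency equals the Bernoulli draw count by construction
  expect_equal(fe@nContact, g$traj@meta$nContact)
  expect_equal(fe@p, g$traj@meta$nContact / 100000)
  ## the estimate sits within sampling error of the target
  expect_lt(abs(fe@p - 0.25), 4 * sqrt(0.25 * 0.75 / 1e5))
  ## independent brute-force counter agrees with the pipeline to 1e-12
  d <- sqrt(rowSums((g$traj@frames[, 2, ] - g$traj@frames[, 1, ])^2))
  pRef <- mean(d < 14)
  dgRef <- -1.9872e-3 * 300 * log(pRef / (1 - pRef))
  expect_equal(fe@dG, dgRef, tolerance = 1e-12)
})

test_that("degenerate contact definitions give bounds, not values", {
  g <- genContactEnsemble(0.5, 500, seed = 7)
  wide <- contactDefinition(1L, 2L, cutoff = 1e9, minPairs = 1)
  feAll <- contactProbability(g$traj, wide, seed = 1)
  expect_equal(feAll@p, 1)
  expect_true(feAll@bound)
  many <- contactDefinition(1L, 2L, cutoff = 14, minPairs = 5L)
  feNone <- contactProbability(g$traj, many, seed = 1)
  expect_equal(feNone@p, 0)
  expect_true(feNone@bound)
  expect_error(contactDefinition(1:3, 3:4), "disjoint")
})

test_that("dG recovery is unbiased on synthetic ensembles", {
  ## point-estimate recovery at three probability scales (the 50-seed CI
  ## coverage property lives in the acceptance layer)
  for (pT in c(0.5, 0.1, 0.01)) {
    g <- genContactEnsemble(pT, 50000, seed = 7)
    fe <- contactProbability(g$traj, g$cdef, seed = 7)
    se <- sqrt(pT * (1 - pT) / 50000)
    expect_lt(abs(fe@p - pT), 4 * se)
    expect_lt(abs(fe@dG - dgTopo(pT)), 0.15)
  }
})

test_that("TL/TLR matrix has full shape and responds to minPairs", {
  traj <- azTraj()
  fx <- azFixture()
  rg <- fx$regions
  loops <- rg[c("L2", "L9")]
  receptors <- rg[c("J8", "J5")]
  m2 <- tlTlrMatrix(traj, loops, receptors, native = c("L2/J8", "L9/J5"),
                    minPairs = 2, seed = 2)
  expect_equal(nrow(m2), 4)
  expect_true(all(is.finite(m2$dG)))
  expect_equal(sum(m2$native), 2)
  ## a stricter contact definition can only raise the penalty
  m4 <- tlTlrMatrix(traj, loops, receptors, minPairs = 4, seed = 2)
  expect_true(all(m4$dG >= m2$dG - 1e-9))
})

test_that("pairwise dG map excludes self-contacts and is symmetric", {
  traj <- azTraj()
  fx <- azFixture()
  mp <- pairwiseDgMap(traj, fx$regions["L9"], seed = 3)
  expect_false(any(mp$residue %in% fx$regions$L9))
  expect_true(all(mp$p >= 0 & mp$p <= 1))
  ## swapping set_i/set_j leaves p unchanged
  cd1 <- contactDefinition(fx$regions$L9, fx$regions$J5, minPairs = 1)
  cd2 <- contactDefinition(fx$regions$J5, fx$regions$L9, minPairs = 1)
  f1 <- contactProbability(traj, cd1, seed = 1)
  f2 <- contactProbability(traj, cd2, seed = 1)
  expect_equal(f1@p, f2@p)
})

test_that("stacking proxy matches an independent classifier on a sweep", {
  traj <- azTraj()
  n <- dim(traj@frames)[1]
  idx <- seq(1, n, length.out = 200)
  flag <- detectP4P6Stacking(traj)[idx]
  ## brute force: recompute beta and the end-gap per frame independently
  esAB <- eulerSeries(traj, "P4", "P6", frames = as.integer(idx))
  beta <- esAB@angles[, 2]
  ha <- traj@helices[["P4"]]; hb <- traj@helices[["P6"]]
  endA <- c(ha$res1[1], rev(ha$res2)[1])      # pair (41, 85) side
  endB <- c(hb$res1[1], rev(hb$res2)[1])      # pair (86, 114) side
  gap <- sapply(seq_along(idx), function(k) {
    f <- idx[k]
    ca <- (traj@frames[f, traj@sRow[endA[1]], ] +
             traj@frames[f, traj@sRow[endA[2]], ]) / 2
    cb <- (traj@frames[f, traj@sRow[endB[1]], ] +
             traj@frames[f, traj@sRow[endB[2]], ]) / 2
    sqrt(sum((ca - cb)^2))
  })
  expect_equal(unname(flag), unname(beta > 150 & gap < 7))
})

test_that("FJC pivot penalty follows the Gaussian-chain form", {
  expect_equal(fjcPivotPenalty(3, 3), 0)
  expect_equal(round(fjcPivotPenalty(2, 4, 300), 2), -0.62)
  pen <- vapply(2:6, function(nb) fjcPivotPenalty(2, nb), numeric(1))
  expect_true(all(diff(pen) < 0))   # more pivots on the far side: worse
  expect_error(fjcPivotPenalty(0, 2), ">= 1")
})
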