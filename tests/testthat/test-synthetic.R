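# Synthetic generators and the fixture library.

test_that("generators are bitwise reproducible under a fixed seed", {
  a <- genIdealChain(20, nFrames = 50, seed = 42)
  b <- genIdealChain(20, nFrames = 50, seed = 42)
  expect_identical(a@frames, b@frames)
  p1 <- genRotationPair(0.4, 100, seed = 11)
  p2 <- genRotationPair(0.4, 100, seed = 11)
  expect_identical(p1[[1]]@angles, p2[[1]]@angles)
  g1 <- genContactEnsemble(0.3, 100, seed = 11)
  g2 <- genContactEnsemble(0.3, 100, seed = 11)
  expect_identical(g1$traj@frames, g2$traj@frames)
})

test_that("ideal chain matches its closed-form ground truth", {
  one <- genIdealChain(1, bondLength = 5, nFrames = 20, seed = 1)
  expect_equal(sqrt(endToEndSq(one)), rep(5, 20))   # n=1: R_ee = b exactly

  tr <- genIdealChain(100, bondLength = 5.36, nFrames = 10000, seed = 2)
  r2 <- endToEndSq(tr)
  expected <- tr@meta$meanRee2
  expect_equal(expected, 100 * 5.36^2)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - expected), 3 * se)
})

test_that("contact ensemble enforces its Bernoulli construction", {
  g <- genContactEnsemble(0.01, 100000, seed = 3)
  d <- sqrt(rowSums((g$traj@frames[, 2, ] - g$traj@frames[, 1, ])^2))
  expect_equal(sum(d < 14), g$traj@meta$nContact)  # exact, by construction
  fe <- contactProbability(g$traj, g$cdef, seed = 1)
  expect_true(fe@ci[1] <= dgTopo(0.01) && dgTopo(0.01) <= fe@ci[2])

  g3 <- genContactEnsemble(0.003, 200000, seed = 4)
  fe3 <- contactProbability(g3$traj, g3$cdef, seed = 1)
  expect_lt(abs(fe3@dG - 3.46), 0.35)
  expect_error(genContactEnsemble(0, 10), "pTarget")
})

test_that("rotation pairs span the correlation range", {
  p1 <- genRotationPair(1, 2000, seed = 5)
  expect_equal(as.numeric(miNorm(p1[[1]], p1[[2]])), 1)
  p0 <- genRotationPair(0, 100000, seed = 5)
  m0 <- miNorm(p0[[1]], p0[[2]])
  expect_lt(as.numeric(m0) - attr(m0, "biasNorm"), 0.02)
  mis <- vapply(c(0, 0.5, 1), function(cc) {
    p <- genRotationPair(cc, 20000, seed = 6)
    as.numeric(miNorm(p[[1]], p[[2]]))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("every fixture re-parses and carries its annotations", {
  for (nm in fixtureNames()) {
    fx <- rnatopoFixture(nm)
    expect_s4_class(fx$ss, "SecondaryStructure")
    expect_true(validObject(fx$ss))
    expect_true(length(fx$regions) >= 1)
  }
  tl <- rnatopoFixture("tltlr")
  expect_equal(tl$restrainedResidues, 26:50)
  ## oligo-U tether and GAAA tetraloop as drawn
  expect_true(all(residues(tl$ss)[tl$regions$tether] == "U"))
  expect_equal(residues(tl$ss)[tl$regions$TL], c("G", "A", "A", "A"))

  az <- rnatopoFixture("azoarcus")
  expect_equal(length(residues(az$ss)), 195)
  expect_equal(residues(az$ss)[az$regions$L2], c("G", "A", "A", "A"))
  expect_equal(residues(az$ss)[az$regions$L9], c("G", "A", "A", "A"))
  ## roster files: the printed NOE counts
  th <- read.table(az$rosterFiles["TH"], sep = "\t", header = TRUE,
                   comment.char = "#", fill = TRUE)
  expect_equal(sum(th$type == "noe"), 8)
  expect_equal(sum(th$type == "dih"), 2)
  l9 <- read.table(az$rosterFiles["L9J5"], sep = "\t", header = TRUE,
                   comment.char = "#", fill = TRUE)
  expect_equal(sum(l9$type == "noe"), 4)
})

test_that("the TLR production restraints carry K = 50 dihedrals", {
  ch <- tlChain()
  rs <- makeRestraints("custom", ch, reference = ch@coords,
                       dihedralResidues = 26:50, K = 50)
  expect_gt(nrow(rs@dihedral), 20)
  expect_true(all(rs@dihedral$K == 50))
  ## all restrained beads belong to residues 26..50
  beads <- unlist(rs@dihedral[c("i", "j", "k", "l")])
  expect_true(all(ch@beads$residue[beads] %in% 26:50))
})
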