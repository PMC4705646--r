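# Chain building: A-form templates, bead tables, rigid groups, restraints,
# PDB mapping.

test_that("A-form helix template has the expected geometry", {
  ff <- forceFieldParams()
  h1 <- buildAformHelix(1, ff)
  expect_equal(nrow(h1$coords), 6)          # 1 bp -> 6 beads, one rigid body

  h11 <- buildAformHelix(11, ff)
  ## P-bead end-to-end of strand 1 approximates 10 helical rises
  p1 <- h11$coords[1, ]; p11 <- h11$coords[31, ]
  axisLen <- sqrt(sum((p1 - p11)^2))
  expect_lt(abs(axisLen - 10 * ffParam(ff, "rise")), 0.5)

  ## determinism: identical runs superimpose exactly
  h11b <- buildAformHelix(11, ff)
  expect_equal(h11$coords, h11b$coords)

  ## cross-pair sugar separation ~ the span of a canonical base pair
  ref <- rnatopo:::aformReference(ff)
  expect_gt(ref$ss_cross, 10); expect_lt(ref$ss_cross, 11)

  ## template is self-avoiding at the configured radii: the steric term of
  ## a freshly built duplex is exactly zero
  res <- rep(seq_len(22), each = 3)
  minD <- Inf
  for (i in seq_len(65)) for (j in (i + 1):66) {
    if (res[i] == res[j]) next
    minD <- min(minD, sqrt(sum((h11$coords[i, ] - h11$coords[j, ])^2)))
  }
  expect_gt(minD, 2 * max(ffParam(ff, "ev_S"), ffParam(ff, "ev_B")))
})

test_that("bead counting and noncanonical-pair handling follow the model", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  expect_equal(nrow(ch@beads), 27)          # 9 residues x 3 beads
  expect_equal(length(ch@groups), 1)

  ## one noncanonical pair: one filler bead and the two fixed NOEs
  ss <- parseStructure("GGGGAAAACCCC",
                       pairs = data.frame(i = c(1:3, 4), j = c(12:10, 9),
                                          class = c(rep("canonical", 3),
                                                    "noncanonical")))
  ch2 <- buildChain(ss, seed = 1)
  expect_equal(nrow(ch2@beads), 3 * 12 + 1)
  noe <- ch2@terms$noe
  expect_equal(nrow(noe), 2)
  expect_equal(sort(noe$rmin), c(5.5, 11))
  expect_equal(sort(noe$rmax), c(7.5, 14))
  expect_true(all(noe$kmin == 2 & noe$fmax == 2))
  ## canonically paired residues carry full-strength backbone dihedrals,
  ## noncanonically paired ones one-fourth strength
  kd <- ffParam(ch2@ff, "k_dihedral")
  expect_true(all(ch2@terms$dihedrals$kc %in% c(kd, kd / 4)))
  ncCentre <- ch2@beads$residue[ch2@terms$dihedrals$j]
  expect_true(all(ch2@terms$dihedrals$kc[ncCentre %in% c(4, 9)] == kd / 4))
  ## attraction only between the paired base beads
  expect_equal(nrow(ch2@terms$attr), 1)
})

test_that("built conformations are closed and overlap-free", {
  ch <- azChain()
  expect_lt(ch@buildInfo$strain, 1.2)
  expect_lt(ch@buildInfo$overlap, 1.2)
  ## rigid groups match their templates exactly (up to the floating-point
  ## limit of fitting at O(100 A) coordinate magnitudes)
  for (nm in names(ch@groups)) {
    idx <- ch@groups[[nm]]
    expect_lt(kabschRmsd(ch@coords[idx, ], ch@templates[[nm]]), 1e-5)
  }
})

test_that("PDB mapping places beads on P/C1'/N atoms and reports gaps", {
  ## synthetic two-residue PDB (an adenosine with all atoms, then a
  ## guanosine missing its phosphate but carrying O5')
  lines <- c(
    "ATOM      1  P     A A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  C1'   A A   1       4.000   5.000   6.000  1.00  0.00",
    "ATOM      3  N9    A A   1       7.000   8.000   9.000  1.00  0.00",
    "ATOM      4  O5'   G A   2      10.000  11.000  12.000  1.00  0.00",
    "ATOM      5  C1'   G A   2      13.000  14.000  15.000  1.00  0.00",
    "ATOM      6  N9    G A   2      16.000  17.000  18.000  1.00  0.00",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  ss <- parseStructure("AG", "..")
  m <- mapPdbToBeads(f, ss)
  expect_equal(m$coords[1, ], c(1, 2, 3))   # P <- P atom
  expect_equal(m$coords[2, ], c(4, 5, 6))   # S <- C1'
  expect_equal(m$coords[3, ], c(7, 8, 9))   # B <- N9 (purine)
  expect_equal(m$coords[4, ], c(10, 11, 12))  # P imputed from O5'
  expect_equal(m$gaps$bead, "P")
  expect_match(m$gaps$note, "O5'")
})

test_that("coarse PDB writing round-trips to output precision", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  f <- tempfile(fileext = ".pdb")
  writeCoarsePDB(ch, f)
  back <- readCoarsePDB(f)
  expect_equal(back$coords, unname(ch@coords), tolerance = 1e-3)
  expect_equal(back$name[1:3], c("P", "S", "B"))
})

test_that("restraint rosters match the printed counts and parameters", {
  ch <- azChain()
  refc <- azReference()
  th <- makeRestraints("TH", ch, reference = refc)
  roster <- th@noe[th@noe$tag == "roster", ]
  expect_equal(nrow(roster), 8)
  expect_equal(nrow(th@dihedral), 2)
  expect_true(all(roster$kmin == 2 & roster$kmax == 2 & roster$fmax == 2))
  expect_true(all(th@dihedral$K == 50))
  expect_true(all(th@noe$rmax - th@noe$rmin == 2))  # measured +/- 1 A

  l9 <- makeRestraints("L9J5", ch, reference = refc)
  expect_equal(nrow(l9@noe[l9@noe$tag == "roster", ]), 4)
  expect_equal(nrow(l9@dihedral), 0)

  rg <- makeRestraints("RG32", ch)
  expect_equal(rg@rg$target, 32)

  ## the roster NOE term is zero when evaluated on the defining reference
  rosterOnly <- new("RestraintSet", kind = "TH", noe = roster,
                    dihedral = th@dihedral, rg = list())
  eAlone <- chainEnergy(ch, refc)
  eWith <- chainEnergy(ch, refc, restraints = rosterOnly)
  expect_equal(eWith[["noe"]], eAlone[["noe"]], tolerance = 1e-9)

  expect_error(makeRestraints("TH", ch), "reference")
})

test_that("building from init coordinates snaps helices and keeps the rest", {
  hp <- rnatopoFixture("hairpin")
  ch <- buildChain(hp$ss, regions = hp$regions, seed = 1)
  init <- ch@coords[seq_len(27), ]
  ch2 <- buildChain(hp$ss, regions = hp$regions, init = init, seed = 1)
  ## the already-consistent conformation is reproduced (helices re-snap
  ## onto identical templates)
  expect_lt(max(abs(ch2@coords - ch@coords)), 1e-6)
  expect_error(buildChain(hp$ss, init = init[1:10, ]), "all")
})
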