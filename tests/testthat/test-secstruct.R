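# Parsing, serialization, topology decomposition and pivot counting.

test_that("dot-bracket parsing reads pairs and validates input", {
  ss <- parseStructure("GGGAAACCC", "(((...)))")
  expect_equal(pairTable(ss)$i, 1:3)
  expect_equal(pairTable(ss)$j, 9:7)
  expect_true(all(pairTable(ss)$class == "canonical"))

  expect_error(parseStructure("GGGAAACC", "(((...))"),
               "unbalanced bracket '\\(' at position 1")
  expect_error(parseStructure("GGGAAACCCC", "(((...))))"),
               "unbalanced bracket")
  expect_error(parseStructure("GGGAAACCC", pairs = data.frame(
    i = c(1, 1), j = c(9, 8))), "more than one pair")
})

test_that("multi-level brackets give crossing pairs and a pseudoknot flag", {
  ss <- parseStructure("GGAAGGAACCAACC", "((..[[..))..]]")
  p <- pairTable(ss)
  expect_setequal(paste(p$i, p$j),
                  c("1 10", "2 9", "5 14", "6 13"))
  ## brute-force crossing check over all pair quadruples
  crossings <- 0L
  for (a in seq_len(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
    i <- p$i[a]; j <- p$j[a]; k <- p$i[b]; l <- p$j[b]
    if ((i < k & k < j & j < l) || (k < i & i < l & l < j))
      crossings <- crossings + 1L
  }
  expect_gt(crossings, 0)
  expect_true(hasPseudoknot(ss))
  expect_false(hasPseudoknot(parseStructure("GGGAAACCC", "(((...)))")))
})

test_that("serialization round-trips pairs, sequence and numbering", {
  fx <- rnatopoFixture("azoarcus")
  expect_warning(db <- asDotBracket(fx$ss), "noncanonical")
  ss2 <- parseStructure(paste(residues(fx$ss), collapse = ""), db)
  can <- pairTable(fx$ss)[pairTable(fx$ss)$class == "canonical", 1:2]
  rownames(can) <- NULL
  expect_equal(pairTable(ss2)[, 1:2], can)

  f <- tempfile(fileext = ".tsv")
  writePairList(fx$ss, f)
  ss3 <- readPairList(f)
  expect_equal(pairTable(ss3), pairTable(fx$ss))
  expect_equal(residues(ss3), residues(fx$ss))
  expect_equal(ss3@numbering, fx$ss@numbering)
})

test_that("topology decomposition finds maximal helices and classifies links", {
  hp <- rnatopoFixture("hairpin")
  tg <- decomposeTopology(hp$ss, hp$regions)
  expect_equal(nrow(helices(tg)), 1)
  expect_equal(sum(tg@units$kind == "linker"), 1)  # terminal loop only

  tw <- rnatopoFixture("twoway")
  tgw <- decomposeTopology(tw$ss, tw$regions)
  expect_equal(nrow(helices(tgw)), 2)
  expect_equal(linkerClass(tgw, "H1", "H2"), "two_way")

  pk <- rnatopoFixture("pseudoknot")
  tgp <- decomposeTopology(pk$ss, pk$regions)
  expect_equal(linkerClass(tgp, "S1", "S2"), "pseudoknot")
})

test_that("helix count matches a brute-force ladder scan on small structures", {
  ladders <- function(ss) {
    p <- pairTable(ss)
    p <- p[p$class == "canonical", ]
    key <- paste(p$i, p$j)
    sum(!(paste(p$i - 1, p$j + 1) %in% key))  # ladder starts
  }
  cases <- list(
    parseStructure("GGGAAACCC", "(((...)))"),
    parseStructure("GGAAGGAACCAACC", "((..[[..))..]]"),
    rnatopoFixture("twoway")$ss,
    parseStructure(strrep("A", 36),
                   "((((...))))..(((...)))...((...))...."))
  for (ss in cases) {
    tg <- decomposeTopology(ss)
    expect_equal(nrow(helices(tg)), ladders(ss))
  }
})

test_that("Azoarcus fixture recovers the published junction classes", {
  fx <- azFixture()
  tg <- decomposeTopology(fx$ss, fx$regions)
  expect_equal(linkerClass(tg, "P3", "P7"), "pseudoknot")
  expect_equal(linkerClass(tg, "P2", "P3"), "single_linker")
  expect_equal(linkerClass(tg, "P4", "P6"), "two_way")
  ## crossing pairs flag both pseudoknotted junctions
  expect_true(hasPseudoknot(fx$ss))
  ## a structure with no crossing pairs reports zero pseudoknot links
  tw <- rnatopoFixture("twoway")
  tgw <- decomposeTopology(tw$ss, tw$regions)
  expect_false(any(c(linkerClass(tgw, "H1", "H2")) == "pseudoknot"))
})

test_that("flexible pivot counts follow the articulation rule", {
  fx <- azFixture()
  tg <- decomposeTopology(fx$ss, fx$regions)
  expect_equal(countFlexiblePivots(tg, "L2", "J8"), 2L)
  expect_equal(countFlexiblePivots(tg, "L9", "J8"), 4L)
  hp <- rnatopoFixture("hairpin")
  tgh <- decomposeTopology(hp$ss, hp$regions)
  expect_equal(countFlexiblePivots(tgh, "loop", "stem"), 0L)
  expect_error(countFlexiblePivots(tg, "L2", "nope"), "unknown region")
})

test_that("residue labels resolve through the numbering map", {
  fx <- azFixture()
  expect_equal(fx$ss@numbering[resolveResidue(fx$ss, "A39")], 39L)
  expect_equal(residues(fx$ss)[resolveResidue(fx$ss, "G116")], "G")
  expect_error(resolveResidue(fx$ss, "A999"), "not in numbering")
  expect_warning(resolveResidue(fx$ss, "C39"), "mismatch")
})
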