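## Fixture structure library: toy structures built in code, plus the two
## data fixtures shipped under inst/extdata (the tethered tetraloop/receptor
## reference system and the Azoarcus ribozyme reconstruction).

#' Names of the shipped fixtures
#' @export
fixtureNames <- function() c("hairpin", "twoway", "pseudoknot", "tltlr",
                             "azoarcus")

#' Fixture structure library
#'
#' Returns a list with the parsed [SecondaryStructure-class] (`ss`), the
#' named region sets (`regions`) and fixture-specific extras:
#' \describe{
#'   \item{hairpin}{9-nt toy hairpin `(((...)))`.}
#'   \item{twoway}{two helices separated by a 3-nt bulge on one strand.}
#'   \item{pseudoknot}{minimal H-type pseudoknot `((..[[..))..]]`.}
#'   \item{tltlr}{the tethered reference system: a GAAA tetraloop hairpin
#'     joined by an oligo-U tether to an 11-nt-receptor hairpin; element
#'     `restrainedResidues` (26-50, the receptor hairpin) is the set held by
#'     backbone dihedral restraints with K = 50 kcal/mol during production.}
#'   \item{azoarcus}{the 195-nt group I ribozyme fixture in crystal-style
#'     numbering (12-206), with helices P2-P9A, loops and joiners, the
#'     noncanonical internal-loop pairs, and the NOE roster files for the
#'     triple helix and L9/J5 (element `rosterFiles`). The pair set is a
#'     reconstruction of the published architecture (see file headers) and
#'     is treated as input data, never hard-coded.}
#' }
#' @param name one of [fixtureNames()]
#' @return list with `ss`, `regions`, and extras
#' @export
rnatopoFixture <- function(name = fixtureNames()) {
  name <- match.arg(name)
  extfile <- function(f) {
    p <- system.file("extdata", f, package = "rnatopo")
    if (!nzchar(p)) stop("fixture file missing: ", f)
    p
  }
  switch(name,
    hairpin = {
      ss <- parseStructure("GGGAAACCC", "(((...)))")
      list(ss = ss,
           regions = list(stem = c(1:3, 7:9), loop = 4:6), name = name)
    },
    twoway = {
      ss <- parseStructure("GCGGAAAGCAGGUUCCUGCCCGC",
                           "((((...((((....))))))))")
      list(ss = ss,
           regions = list(H1 = c(1:4, 20:23), bulge = 5:7,
                          H2 = c(8:11, 16:19), loop = 12:15),
           name = name)
    },
    pseudoknot = {
      ss <- parseStructure("GGAAGGAACCAACC", "((..[[..))..]]")
      list(ss = ss,
           regions = list(S1 = c(1:2, 9:10), S2 = c(5:6, 13:14)),
           name = name)
    },
    tltlr = {
      ss <- readPairList(extfile("tltlr_pairs.tsv"))
      regions <- readRegions(extfile("tltlr_regions.tsv"), ss)
      list(ss = ss, regions = regions, restrainedResidues = 26:50,
           name = name)
    },
    azoarcus = {
      ss <- readPairList(extfile("azoarcus_pairs.tsv"))
      regions <- readRegions(extfile("azoarcus_regions.tsv"), ss)
      list(ss = ss, regions = regions,
           rosterFiles = c(TH = extfile("azoarcus_noe_th.tsv"),
                           L9J5 = extfile("azoarcus_noe_l9j5.tsv")),
           name = name)
    })
}
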