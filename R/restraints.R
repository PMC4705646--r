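## Restraint construction: the printed NOE rosters (triple helix, L9/J5),
## the radius-of-gyration restraint, and custom NOE / backbone-dihedral
## restraint sets.

.emptyNoe <- function() data.frame(i = integer(), j = integer(),
                                   rmin = numeric(), rmax = numeric(),
                                   kmin = numeric(), kmax = numeric(),
                                   fmax = numeric(), tag = character())

## Auxiliary coaxial-continuation restraints for a directly bonded helix
## junction (residues r1 | r2 across the junction bond). The two printed
## backbone dihedrals fix the torsional coordinates, but the rigid-body
## model's junction *bending* is much softer than in a force field whose
## backbone potentials themselves hold A-form geometry; these distance
## restraints between the junction pairs' far-strand beads express the same
## stacked continuation and stand in for that stiffness.
.stackAux <- function(chain, r1, r2) {
  p <- chain@ss@pairs[chain@ss@pairs$class == "canonical", ]
  partner <- function(r) {
    hit <- c(p$j[p$i == r], p$i[p$j == r])
    if (!length(hit)) stop("junction residue is not canonically paired: ", r)
    hit[1]
  }
  q1 <- partner(r1); q2 <- partner(r2)
  ## exact target distances from the ideal continuation: (r1, r2) map onto
  ## adjacent strand-1 residues of one duplex, (q1, q2) onto their partners
  tpl <- buildAformHelix(8, chain@ff)$coords
  S1 <- function(k) tpl[3 * k - 1, ]
  S2 <- function(k) tpl[3 * (17 - k) - 1, ]
  P2_ <- function(k) tpl[3 * (17 - k) - 2, ]
  B2_ <- function(k) tpl[3 * (17 - k), ]
  d <- function(a, b) sqrt(sum((a - b)^2))
  targets <- c(d(P2_(4), P2_(5)),      # P(q1)-P(q2)
               d(S2(4), S2(5)),        # S(q1)-S(q2)
               d(B2_(4), B2_(5)),      # B(q1)-B(q2)
               d(S1(4), S2(5)),        # S(r1)-S(q2) diagonal
               d(S2(4), S1(5)))        # S(q1)-S(r2) diagonal
  data.frame(i = c(.pIdx(q1), .sIdx(q1), .bIdx(q1), .sIdx(r1), .sIdx(q1)),
             j = c(.pIdx(q2), .sIdx(q2), .bIdx(q2), .sIdx(q2), .sIdx(r2)),
             rmin = targets - 1, rmax = targets + 1,
             kmin = 5, kmax = 5, fmax = 10, tag = "stack")
}
.emptyDih <- function() data.frame(i = integer(), j = integer(),
                                   k = integer(), l = integer(),
                                   phi0 = numeric(), K = numeric())

.beadFromLabel <- function(chain, label) {
  ## "S85", "P86", "B39" -> bead index (number in external numbering)
  type <- substr(label, 1, 1)
  res <- resolveResidue(chain@ss, substr(label, 2, nchar(label)))
  switch(type, P = .pIdx(res), S = .sIdx(res), B = .bIdx(res),
         stop("bad bead label: ", label))
}

#' Build a restraint set
#'
#' Kinds:
#' \describe{
#'   \item{TH}{the triple-helix roster: 8 S-bead NOEs docking J3/4 onto P6
#'     and J6/7 onto P4, plus the two backbone dihedrals separating P4 and
#'     P6 restrained to the coaxially stacked (ideal A-form continuation)
#'     values with `K = 50` kcal/mol.}
#'   \item{L9J5}{4 S-bead NOEs docking the L9 tetraloop onto the J5
#'     receptor.}
#'   \item{RG32}{a single collective restraint holding the all-bead radius
#'     of gyration at 32 A.}
#'   \item{custom}{caller-supplied NOE pairs and/or a residue range whose
#'     backbone dihedrals are restrained to their values in `reference`
#'     (the tetraloop-receptor reference system uses this for its receptor
#'     hairpin).}
#' }
#' NOE windows are set to +/- 1 A of the distance measured in `reference`
#' (required for TH/L9J5), with `f_max = k_min = k_max = 2` kcal/mol/A^2.
#'
#' @param kind one of "TH", "L9J5", "RG32", "custom"
#' @param chain [CoarseChain-class]
#' @param reference coordinates supplying target distances/dihedrals
#'   (n_beads x 3); for TH/L9J5 typically a docked native-like conformation
#' @param rosterFile TSV with columns `type` (`noe`/`dih`) and bead/residue
#'   labels; defaults to the shipped roster for TH/L9J5
#' @param noe data.frame of residue-label pairs (`a`, `b`) for custom NOEs
#'   between S beads
#' @param dihedralResidues residue positions (1-based) whose backbone
#'   dihedrals get restrained (custom)
#' @param K dihedral restraint constant, kcal/mol
#' @param rgTarget,rgK radius-of-gyration target (A) and force constant
#' @return [RestraintSet-class]
#' @export
makeRestraints <- function(kind = c("TH", "L9J5", "RG32", "custom"),
                           chain, reference = NULL, rosterFile = NULL,
                           noe = NULL, dihedralResidues = NULL, K = 50,
                           rgTarget = 32, rgK = 0.5) {
  kind <- match.arg(kind)
  if (kind == "RG32")
    return(new("RestraintSet", kind = kind, noe = .emptyNoe(),
               dihedral = .emptyDih(), rg = list(target = rgTarget, k = rgK)))
  noeTab <- .emptyNoe(); dihTab <- .emptyDih()
  dist <- function(i, j) sqrt(sum((reference[i, ] - reference[j, ])^2))
  if (kind %in% c("TH", "L9J5")) {
    if (is.null(reference))
      stop(kind, " restraints need reference coordinates for the target ",
           "distances (see syntheticNativeReference)")
    if (is.null(rosterFile))
      rosterFile <- system.file("extdata",
                                sprintf("azoarcus_noe_%s.tsv",
                                        tolower(kind)), package = "rnatopo")
    ros <- read.table(rosterFile, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE,
                      fill = TRUE)
    junction <- NULL
    for (r in seq_len(nrow(ros))) {
      if (ros$type[r] == "noe") {
        i <- .sIdx(resolveResidue(chain@ss, ros$a[r]))
        j <- .sIdx(resolveResidue(chain@ss, ros$b[r]))
        d <- dist(i, j)
        noeTab <- rbind(noeTab, data.frame(i = i, j = j, rmin = d - 1,
                                           rmax = d + 1, kmin = 2, kmax = 2,
                                           fmax = 2, tag = "roster"))
      } else if (ros$type[r] == "dih") {
        beads <- vapply(strsplit(trimws(ros$a[r]), "\\s+")[[1]],
                        function(x) .beadFromLabel(chain, x), integer(1))
        ## target: the ideal A-form continuation (coaxial stack) value
        ref <- aformReference(chain@ff)
        phi0 <- if (chain@beads$type[beads[1]] == "S") ref$phi_SPSP
                else ref$phi_PSPS
        dihTab <- rbind(dihTab, data.frame(i = beads[1], j = beads[2],
                                           k = beads[3], l = beads[4],
                                           phi0 = phi0, K = K))
        junction <- sort(unique(chain@beads$residue[beads]))
      }
    }
    if (kind == "TH" && !is.null(junction))
      noeTab <- rbind(noeTab, .stackAux(chain, junction[1], junction[2]))
  }
  if (kind == "custom") {
    if (!is.null(noe)) {
      if (is.null(reference))
        stop("custom NOEs need reference coordinates")
      for (r in seq_len(nrow(noe))) {
        i <- .sIdx(resolveResidue(chain@ss, noe$a[r]))
        j <- .sIdx(resolveResidue(chain@ss, noe$b[r]))
        d <- dist(i, j)
        noeTab <- rbind(noeTab, data.frame(i = i, j = j, rmin = d - 1,
                                           rmax = d + 1, kmin = 2, kmax = 2,
                                           fmax = 2, tag = "custom"))
      }
    }
    if (!is.null(dihedralResidues)) {
      if (is.null(reference))
        stop("dihedral restraints need reference coordinates")
      bb <- chain@moves$backbone
      pos <- which(chain@beads$residue[bb] %in% dihedralResidues)
      pos <- pos[pos + 3L <= length(bb)]
      pos <- pos[(pos + 3L) %in% which(chain@beads$residue[bb] %in%
                                         dihedralResidues)]
      for (t in pos) {
        q <- bb[t:(t + 3L)]
        phi0 <- .dihedralDeg(reference[q[1], ], reference[q[2], ],
                             reference[q[3], ], reference[q[4], ])
        dihTab <- rbind(dihTab, data.frame(i = q[1], j = q[2], k = q[3],
                                           l = q[4], phi0 = phi0, K = K))
      }
    }
  }
  new("RestraintSet", kind = kind, noe = noeTab, dihedral = dihTab,
      rg = list())
}

.dihedralDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Generate a synthetic docked reference conformation
#'
#' Produces a native-like conformation in which the requested tertiary
#' contacts are formed, by running a short downhill Monte Carlo schedule
#' under wide funnel restraints that pull the roster S-bead pairs into
#' docking range and (for the triple helix) stack P4 on P6. This is a
#' synthetic stand-in for crystal-structure coordinates: it supplies the
#' reference distances that parameterize [makeRestraints()] when no
#' experimental structure is available, and is labelled as such in all
#' outputs.
#'
#' @param chain [CoarseChain-class] (the Azoarcus fixture chain)
#' @param kinds restraint rosters to dock ("TH", "L9J5" or both)
#' @param seed integer
#' @return coordinates matrix (n_beads x 3) with `synthetic = TRUE` attribute
#' @export
syntheticNativeReference <- function(chain, kinds = c("TH", "L9J5"),
                                     seed = 1L) {
  noeTab <- .emptyNoe(); dihTab <- .emptyDih(); stackTab <- .emptyNoe()
  ref <- aformReference(chain@ff)
  for (kind in kinds) {
    rosterFile <- system.file("extdata",
                              sprintf("azoarcus_noe_%s.tsv", tolower(kind)),
                              package = "rnatopo")
    ros <- read.table(rosterFile, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE,
                      fill = TRUE)
    junction <- NULL
    for (r in seq_len(nrow(ros))) {
      if (ros$type[r] == "noe") {
        i <- .sIdx(resolveResidue(chain@ss, ros$a[r]))
        j <- .sIdx(resolveResidue(chain@ss, ros$b[r]))
        ## wide funnel pulls: docking only, never used in production; kept
        ## gentle enough not to fight the junction-stacking restraints
        noeTab <- rbind(noeTab, data.frame(i = i, j = j, rmin = 3,
                                           rmax = 11, kmin = 5, kmax = 5,
                                           fmax = 10, tag = "pull"))
      } else if (ros$type[r] == "dih") {
        beads <- vapply(strsplit(trimws(ros$a[r]), "\\s+")[[1]],
                        function(x) .beadFromLabel(chain, x), integer(1))
        phi0 <- if (chain@beads$type[beads[1]] == "S") ref$phi_SPSP
                else ref$phi_PSPS
        dihTab <- rbind(dihTab, data.frame(i = beads[1], j = beads[2],
                                           k = beads[3], l = beads[4],
                                           phi0 = phi0, K = 50))
        junction <- sort(unique(chain@beads$residue[beads]))
      }
    }
    if (!is.null(junction))
      stackTab <- rbind(stackTab, .stackAux(chain, junction[1], junction[2]))
  }
  pull <- new("RestraintSet", kind = "custom",
              noe = rbind(noeTab, stackTab), dihedral = dihTab, rg = list())
  stackOnly <- new("RestraintSet", kind = "custom", noe = stackTab,
                   dihedral = dihTab, rg = list())
  stage <- 0L
  run <- function(coords, restr, T, moves, sd) {
    stage <<- stage + 1L
    sys <- .sysList(chain, restraints = restr)
    out <- .cppRemdRun(sys, coords, T, 1L, as.integer(moves), 0L,
                       integer(0), sd * 100 + stage, 1L)
    out$finalCoords[[1]]
  }
  worst <- function(coords) {
    if (!nrow(noeTab)) return(0)
    max(sqrt(rowSums((coords[noeTab$i, , drop = FALSE] -
                        coords[noeTab$j, , drop = FALSE])^2)))
  }
  ## a TH reference must also be coaxially stacked at P4/P6, or the
  ## measured NOE windows would lock in a bent, self-inconsistent state
  hnames <- chain@topology@helices$name
  checkStack <- nrow(dihTab) > 0 && all(c("P4", "P6") %in% hnames)
  stacked <- function(coords) {
    if (!checkStack) return(TRUE)
    fa <- helixFrame(chain, "P4", coords)
    fb <- helixFrame(chain, "P6", coords)
    beta <- eulerAngles(fa, fb)[["beta"]]
    h <- chain@topology@helices
    pa <- h[h$name == "P4", ]; pb <- h[h$name == "P6", ]
    endA <- c(pa$s1_start, pa$s2_end); endB <- c(pb$s1_start, pb$s2_end)
    gap <- sqrt(sum((colMeans(coords[.sIdx(endA), , drop = FALSE]) -
                       colMeans(coords[.sIdx(endB), , drop = FALSE]))^2))
    ## enforced-stack geometry in this model: near-coaxial with ~10-15 deg
    ## of residual hinging allowed by the restraint windows
    beta > 125 && gap < 8
  }
  best <- NULL; bestScore <- c(FALSE, Inf)
  for (attempt in seq_len(6L)) {
    sd <- seed + 1000L * (attempt - 1L)
    coords <- chain@coords
    ## form the junction stack first, then funnel the dockings in while
    ## cooling, and finish with a cold stage under the full restraint set
    coords <- run(coords, stackOnly, 500, 50000L, sd)
    for (T in c(450, 350, 300, 250, 200, 150))
      coords <- run(coords, pull, T, 80000L, sd)
    coords <- run(coords, pull, 120, 60000L, sd)
    d <- worst(coords); st <- stacked(coords)
    if ((st && !bestScore[1]) || (st == bestScore[1] && d < bestScore[2])) {
      best <- coords; bestScore <- c(st, d)
    }
    if (bestScore[1] && bestScore[2] <= 12.5) break
  }
  if (!bestScore[1] || bestScore[2] > 12.5)
    warning(sprintf(paste0("docking incomplete: worst roster distance ",
                           "%.1f A, stacked = %s; consider another seed"),
                    bestScore[2], bestScore[1]))
  coords <- best
  attr(coords, "synthetic") <- TRUE
  attr(coords, "worstDock") <- bestScore[2]
  attr(coords, "stacked") <- as.logical(bestScore[1])
  coords
}

#' Export a restraint roster as TSV
#' @param restraints [RestraintSet-class]; @param chain the chain the bead
#'   indices refer to; @param file path
#' @export
writeRestraintTSV <- function(restraints, chain, file) {
  lab <- function(i) paste0(chain@beads$type[i],
                            chain@ss@numbering[chain@beads$residue[i]])
  con <- file(file, "w"); on.exit(close(con))
  writeLines("# restraint roster export", con)
  writeLines("type\ta\tb\trmin\trmax\tk\tfmax_or_K", con)
  no <- restraints@noe
  for (r in seq_len(nrow(no)))
    writeLines(sprintf("noe\t%s\t%s\t%.2f\t%.2f\t%.2f\t%.2f", lab(no$i[r]),
                       lab(no$j[r]), no$rmin[r], no$rmax[r], no$kmin[r],
                       no$fmax[r]), con)
  dh <- restraints@dihedral
  for (r in seq_len(nrow(dh)))
    writeLines(sprintf("dih\t%s %s %s %s\t\t%.2f\t\t\t%.2f",
                       lab(dh$i[r]), lab(dh$j[r]), lab(dh$k[r]),
                       lab(dh$l[r]), dh$phi0[r], dh$K[r]), con)
  invisible(file)
}
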