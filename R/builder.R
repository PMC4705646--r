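## Chain building: bead tables, rigid groups, energy terms, move tables,
## initial layout and relaxation, PDB bead mapping.

.pIdx <- function(r) 3L * r - 2L
.sIdx <- function(r) 3L * r - 1L
.bIdx <- function(r) 3L * r

.beadTable <- function(ss) {
  n <- length(ss@sequence)
  beads <- data.frame(residue = rep(seq_len(n), each = 3L),
                      type = rep(c("P", "S", "B"), n),
                      stringsAsFactors = FALSE)
  nc <- ss@pairs[ss@pairs$class == "noncanonical", , drop = FALSE]
  b2Owner <- integer(0)
  if (nrow(nc)) {
    ## the steric filler bead goes on the purine if exactly one member is a
    ## purine, else on the 5'-most residue
    for (k in seq_len(nrow(nc))) {
      pur <- ss@sequence[c(nc$i[k], nc$j[k])] %in% c("A", "G")
      owner <- if (sum(pur) == 1) c(nc$i[k], nc$j[k])[pur] else nc$i[k]
      b2Owner <- c(b2Owner, owner)
    }
    beads <- rbind(beads, data.frame(residue = b2Owner, type = "B2"))
  }
  rownames(beads) <- NULL
  list(beads = beads, b2Owner = b2Owner)
}

.assembleTerms <- function(ss, tg, ff, beads, group, b2Owner, ref) {
  n <- length(ss@sequence)
  p <- ff@params
  sameGroup <- function(i, j) group[i] > 0L & group[i] == group[j]
  ## bonds
  bonds <- rbind(
    data.frame(i = .pIdx(1:n), j = .sIdx(1:n), b0 = ref$b_PS, k = p$k_bond),
    if (n > 1) data.frame(i = .sIdx(1:(n - 1)), j = .pIdx(2:n),
                          b0 = ref$b_SP, k = p$k_bond),
    data.frame(i = .sIdx(1:n), j = .bIdx(1:n), b0 = ref$b_SB, k = p$k_bond))
  if (length(b2Owner))
    bonds <- rbind(bonds, data.frame(i = .bIdx(b2Owner),
                                     j = 3L * n + seq_along(b2Owner),
                                     b0 = p$b2_bond, k = p$k_bond))
  bonds <- bonds[!sameGroup(bonds$i, bonds$j), , drop = FALSE]
  ## backbone angle potentials belong to paired residues only: unpaired
  ## nucleotides are freely rotatable chains. A term survives when its
  ## central bead sits on a canonically paired residue and the term is not
  ## entirely inside one rigid group (where it would be constant).
  canonical <- ss@pairs[ss@pairs$class == "canonical", , drop = FALSE]
  pairedRes <- rep(FALSE, n)
  pairedRes[c(canonical$i, canonical$j)] <- TRUE
  angles <- data.frame(i = integer(), j = integer(), k_ = integer(),
                       t0 = numeric(), kc = numeric())
  if (n > 1) {
    a1 <- data.frame(i = .pIdx(1:(n - 1)), j = .sIdx(1:(n - 1)),
                     k_ = .pIdx(2:n), t0 = ref$theta_PSP, kc = p$k_angle,
                     ctr = 1:(n - 1))
    a2 <- data.frame(i = .sIdx(1:(n - 1)), j = .pIdx(2:n), k_ = .sIdx(2:n),
                     t0 = ref$theta_SPS, kc = p$k_angle, ctr = 2:n)
    angles <- rbind(a1, a2)
    allIn <- sameGroup(angles$i, angles$j) & sameGroup(angles$j, angles$k_)
    angles <- angles[!allIn & pairedRes[angles$ctr], , drop = FALSE]
    angles$ctr <- NULL
  }
  ## backbone dihedrals: canonically paired residues carry them at full
  ## strength (only the terms bridging two rigid groups survive, e.g. the
  ## two dihedrals separating directly bonded helices); noncanonically
  ## paired residues at one-fourth strength; unpaired residues none.
  nc <- ss@pairs[ss@pairs$class == "noncanonical", , drop = FALSE]
  dihRows <- function(r, kc) {
    out <- list()
    if (r > 1)
      out[[1]] <- data.frame(i = .sIdx(r - 1L), j = .pIdx(r), k_ = .sIdx(r),
                             l = .pIdx(r + 1L), phi0 = ref$phi_SPSP, kc = kc)
    if (r < n)
      out[[length(out) + 1L]] <- data.frame(
        i = .pIdx(r), j = .sIdx(r), k_ = .pIdx(r + 1L), l = .sIdx(r + 1L),
        phi0 = ref$phi_PSPS, kc = kc)
    out
  }
  rows <- list()
  for (r in sort(unique(c(nc$i, nc$j))))
    rows <- c(rows, dihRows(r, p$k_dihedral_noncanonical))
  for (r in which(pairedRes))
    rows <- c(rows, dihRows(r, p$k_dihedral))
  dihedrals <- if (length(rows)) do.call(rbind, rows)
               else data.frame(i = integer(), j = integer(), k_ = integer(),
                               l = integer(), phi0 = numeric(),
                               kc = numeric())
  if (nrow(dihedrals)) {
    dihedrals <- dihedrals[dihedrals$l <= 3L * n & dihedrals$i >= 1L, ,
                           drop = FALSE]
    ## drop terms wholly inside one rigid group (constant) and terms whose
    ## beads span four different flexible residues (unpaired backbone)
    allIn <- sameGroup(dihedrals$i, dihedrals$j) &
      sameGroup(dihedrals$j, dihedrals$k_) &
      sameGroup(dihedrals$k_, dihedrals$l)
    dihedrals <- dihedrals[!allIn, , drop = FALSE]
    rownames(dihedrals) <- NULL
  }
  ## fixed internal restraints and attraction of noncanonical pairs
  noe <- data.frame(i = integer(), j = integer(), rmin = numeric(),
                    rmax = numeric(), kmin = numeric(), kmax = numeric(),
                    fmax = numeric())
  attr <- data.frame(i = integer(), j = integer(), eps = numeric(),
                     r0 = numeric(), w = numeric())
  if (nrow(nc)) {
    noe <- rbind(
      data.frame(i = .bIdx(nc$i), j = .bIdx(nc$j), rmin = 5.5, rmax = 7.5,
                 kmin = p$nc_noe_k, kmax = p$nc_noe_k, fmax = p$nc_noe_fmax),
      data.frame(i = .sIdx(nc$i), j = .sIdx(nc$j), rmin = 11, rmax = 14,
                 kmin = p$nc_noe_k, kmax = p$nc_noe_k, fmax = p$nc_noe_fmax))
    attr <- data.frame(i = .bIdx(nc$i), j = .bIdx(nc$j), eps = p$attr_eps,
                       r0 = p$attr_r0, w = p$attr_w)
  }
  evRad <- .evRadius(ff, beads$type)
  list(bonds = bonds, angles = angles, dihedrals = dihedrals, noe = noe,
       attr = attr, evRad = evRad)
}

## rigid groups + templates, one per canonical helix
.makeGroups <- function(tg, ff) {
  h <- tg@helices
  groups <- list(); templates <- list()
  for (k in seq_len(nrow(h))) {
    s1 <- seq(h$s1_start[k], h$s1_end[k])
    s2 <- seq(h$s2_start[k], h$s2_end[k])
    beads <- c(rbind(.pIdx(s1), .sIdx(s1), .bIdx(s1)),
               rbind(.pIdx(s2), .sIdx(s2), .bIdx(s2)))
    groups[[h$name[k]]] <- as.integer(beads)
    templates[[h$name[k]]] <- buildAformHelix(h$n_bp[k], ff)$coords
  }
  list(groups = groups, templates = templates)
}

## ---- move tables --------------------------------------------------------

.moveTables <- function(ss, beads, group, b2Owner, bonds) {
  n <- length(ss@sequence)
  nb <- nrow(beads)
  backbone <- as.integer(rbind(.pIdx(1:n), .sIdx(1:n)))
  ## contracted connectivity graph: rigid groups become single nodes
  nodeOf <- ifelse(group > 0L, paste0("g", group), paste0("b", seq_len(nb)))
  eF <- nodeOf[bonds$i]; eT <- nodeOf[bonds$j]
  keep <- eF != eT
  g <- igraph::graph_from_data_frame(
    data.frame(from = eF[keep], to = eT[keep]), directed = FALSE,
    vertices = data.frame(name = unique(nodeOf)))
  ## free hinges = bridges of the contracted graph
  brIds <- as.integer(igraph::bridges(g))
  pivotAxis <- integer(0); pivotSets <- list()
  beadsOfNode <- split(seq_len(nb), nodeOf)
  bondRow <- which(keep)
  for (eid in brIds) {
    bi <- bonds$i[bondRow[eid]]; bj <- bonds$j[bondRow[eid]]
    g2 <- igraph::delete_edges(g, eid)
    comp <- igraph::components(g2)$membership
    sideI <- names(comp)[comp == comp[nodeOf[bi]]]
    sideJ <- names(comp)[comp == comp[nodeOf[bj]]]
    if (length(sideJ) <= length(sideI)) {
      movedNodes <- sideJ; axisBead <- bi
    } else {
      movedNodes <- sideI; axisBead <- bj
    }
    set <- sort(unlist(beadsOfNode[movedNodes], use.names = FALSE))
    ## one/two-bead sets are covered by local displacement moves
    if (length(set) >= 3 && length(set) < nb) {
      pivotAxis <- c(pivotAxis, axisBead)
      pivotSets[[length(pivotSets) + 1L]] <- as.integer(set)
    }
  }
  ## two-point segment rotations between flexible backbone bonds
  bbPos <- integer(nb); bbPos[backbone] <- seq_along(backbone)
  flex <- which(vapply(seq_len(2L * n - 1L), function(t) {
    i <- backbone[t]; j <- backbone[t + 1L]
    !(group[i] > 0L && group[i] == group[j])
  }, logical(1)))
  segments <- data.frame(u = integer(), v = integer(), a = integer(),
                         b = integer())
  if (length(flex) >= 2) {
    cand <- t(utils::combn(flex, 2L))
    a <- cand[, 1] + 1L; b <- cand[, 2]
    ok <- rep(TRUE, nrow(cand))
    for (gid in unique(group[group > 0L])) {
      res <- sort(unique(beads$residue[group == gid]))
      runs <- split(res, cumsum(c(1L, diff(res) != 1L)))
      inside <- rep(0L, nrow(cand)); tot <- 0L
      for (run in runs) {
        lo <- bbPos[.pIdx(run[1])]; hi <- bbPos[.sIdx(run[length(run)])]
        len <- hi - lo + 1L
        tot <- tot + len
        ov <- pmax(0L, pmin(b, hi) - pmax(a, lo) + 1L)
        inside <- inside + ov
      }
      ok <- ok & (inside == 0L | inside == tot)
    }
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      segments <- data.frame(u = backbone[cand[, 1]],
                             v = backbone[cand[, 2] + 1L],
                             a = cand[, 1] + 1L, b = cand[, 2])
      segments <- segments[segments$b >= segments$a, , drop = FALSE]
    }
  }
  b2OfRes <- integer(n)
  if (length(b2Owner)) b2OfRes[b2Owner] <- 3L * n + seq_along(b2Owner)
  list(pivotAxis = pivotAxis, pivotSets = pivotSets, segments = segments,
       localBeads = which(group == 0L), backbone = backbone,
       bOfRes = .bIdx(1:n), b2OfRes = b2OfRes)
}

## ---- system list for the compiled core ---------------------------------

.sysList <- function(chain, restraints = NULL, ev = TRUE, angles = TRUE,
                     evScale = 1, weights = NULL, amplitudes = NULL) {
  tm <- chain@terms
  mv <- chain@moves
  p <- chain@ff@params
  noe <- tm$noe; dr <- data.frame(i = integer(), j = integer(),
                                  k_ = integer(), l = integer(),
                                  phi0 = numeric(), K = numeric())
  rgOn <- FALSE; rgTarget <- 1; rgK <- 0
  if (!is.null(restraints)) {
    if (nrow(restraints@noe)) {
      rn <- restraints@noe
      noe <- rbind(noe, data.frame(i = rn$i, j = rn$j, rmin = rn$rmin,
                                   rmax = rn$rmax, kmin = rn$kmin,
                                   kmax = rn$kmax, fmax = rn$fmax))
    }
    if (nrow(restraints@dihedral)) {
      rd <- restraints@dihedral
      dr <- data.frame(i = rd$i, j = rd$j, k_ = rd$k, l = rd$l,
                       phi0 = rd$phi0, K = rd$K)
    }
    if (length(restraints@rg)) {
      rgOn <- TRUE; rgTarget <- restraints@rg$target; rgK <- restraints@rg$k
    }
  }
  ang <- if (angles) tm$angles else tm$angles[0, , drop = FALSE]
  if (is.null(weights)) weights <- c(0.25, 0.25, 0.15, 0.35)
  if (is.null(amplitudes)) amplitudes <- c(45, 40, 3, 0.35, 0.6)
  deg2rad <- pi / 180
  list(nb = nrow(chain@beads),
       resid = as.integer(chain@beads$residue),
       btype = match(chain@beads$type, c("P", "S", "B", "B2")) - 1L,
       group = as.integer(chain@group),
       bondI = tm$bonds$i, bondJ = tm$bonds$j, bondB0 = tm$bonds$b0,
       bondK = tm$bonds$k,
       angI = ang$i, angJ = ang$j, angK = ang$k_,
       angT0 = ang$t0 * deg2rad, angKc = ang$kc,
       dihI = tm$dihedrals$i, dihJ = tm$dihedrals$j, dihK = tm$dihedrals$k_,
       dihL = tm$dihedrals$l, dihPhi0 = tm$dihedrals$phi0 * deg2rad,
       dihKc = tm$dihedrals$kc,
       attrI = tm$attr$i, attrJ = tm$attr$j, attrEps = tm$attr$eps,
       attrR0 = tm$attr$r0, attrW = tm$attr$w,
       noeI = noe$i, noeJ = noe$j, noeRmin = noe$rmin, noeRmax = noe$rmax,
       noeKmin = noe$kmin, noeKmax = noe$kmax, noeFmax = noe$fmax,
       drI = dr$i, drJ = dr$j, drK = dr$k_, drL = dr$l,
       drPhi0 = dr$phi0 * deg2rad, drKc = dr$K,
       evRad = tm$evRad, evK = p$k_ev * evScale, evOn = isTRUE(ev) && evScale > 0,
       rgOn = rgOn, rgTarget = rgTarget, rgK = rgK,
       pivotAxis = mv$pivotAxis, pivotSets = mv$pivotSets,
       segU = mv$segments$u, segV = mv$segments$v,
       segA = mv$segments$a, segB = mv$segments$b,
       helixSets = unname(chain@groups),
       localBeads = mv$localBeads,
       backbone = mv$backbone, bOfRes = mv$bOfRes, b2OfRes = mv$b2OfRes,
       groupBeads = unname(chain@groups),
       groupTpl = unname(chain@templates),
       moveWeights = weights, amplitudes = amplitudes)
}

## ---- initial layout -----------------------------------------------------

.unitPerp <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- a - sum(a * v) * v
  p / sqrt(sum(p^2))
}

.rotAbout <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2)); t <- deg * pi / 180
  c_ <- cos(t); s <- sin(t); C <- 1 - c_
  matrix(c(a[1]^2*C + c_, a[1]*a[2]*C - a[3]*s, a[1]*a[3]*C + a[2]*s,
           a[1]*a[2]*C + a[3]*s, a[2]^2*C + c_, a[2]*a[3]*C - a[1]*s,
           a[1]*a[3]*C - a[2]*s, a[2]*a[3]*C + a[1]*s, a[3]^2*C + c_),
         3, 3, byrow = TRUE)
}

.arcPoints <- function(A, B, npts, bond = 5.36, perpSeed = c(0, 0, 1)) {
  chord <- B - A; c_ <- sqrt(sum(chord^2))
  if (c_ < 1e-6) chord <- c(1e-3, 0, 0)
  cd <- chord / max(c_, 1e-6)
  Lreq <- bond * (npts + 1)
  perp <- perpSeed - sum(perpSeed * cd) * cd
  if (sqrt(sum(perp^2)) < 1e-6) perp <- .unitPerp(cd)
  perp <- perp / sqrt(sum(perp^2))
  if (c_ >= Lreq) {
    t <- seq_len(npts) / (npts + 1)
    return(t(sapply(t, function(tt) A + chord * tt)))
  }
  a <- sqrt(max(0, 2 * (Lreq / pi)^2 - (c_ / 2)^2))
  t <- pi * seq_len(npts) / (npts + 1)
  t(sapply(t, function(tt)
    A + cd * (c_ / 2) * (1 - cos(tt)) + perp * a * sin(tt)))
}

.layoutChain <- function(ss, tg, groups, templates, ff, ref, seed) {
  n <- length(ss@sequence)
  nb <- 3L * n + sum(ss@pairs$class == "noncanonical")
  coords <- matrix(NA_real_, nb, 3)
  placed <- logical(n)
  h <- tg@helices
  helixOfS1 <- integer(n)
  if (nrow(h)) helixOfS1[h$s1_start] <- seq_len(nrow(h))
  oldseed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = .GlobalEnv))
  set.seed(seed)
  rng <- function(k = 1) runif(k)
  pos <- c(0, 0, 0); dir <- c(1, 0, 0)
  fanCount <- 0L
  bond <- (ref$b_PS + ref$b_SP) / 2

  placeHelix <- function(hk, attach, growDir) {
    s1 <- seq(h$s1_start[hk], h$s1_end[hk])
    s2 <- seq(h$s2_start[hk], h$s2_end[hk])
    tpl <- templates[[h$name[hk]]]
    ## aim the axis at the first already-placed residue enclosed by the helix
    interior <- setdiff(seq(h$s1_end[hk] + 1L, h$s2_start[hk] - 1L), 0L)
    target <- interior[placed[interior]][1]
    if (!is.na(target) && length(target)) {
      v <- coords[.sIdx(target), ] - attach
      nv <- sqrt(sum(v^2))
      axisDir <- if (nv > 1) v / nv else growDir
    } else {
      fanCount <<- fanCount + 1L
      axAngle <- 40 + 30 * ((fanCount %% 3))
      axPerp <- .unitPerp(growDir)
      axPerp <- .rotAbout(growDir, 360 * rng()) %*% axPerp
      axisDir <- as.numeric(.rotAbout(as.numeric(axPerp), axAngle) %*% growDir)
    }
    x1 <- .unitPerp(axisDir)
    Rb <- cbind(x1, .cross(axisDir, x1), axisDir)
    anchorRow <- 1L  # P bead of strand-1 first residue
    t0 <- (attach + growDir * bond) - as.numeric(Rb %*% tpl[anchorRow, ])
    xyz <- t(Rb %*% t(tpl)) + matrix(t0, nrow(tpl), 3, byrow = TRUE)
    resOrder <- c(s1, s2)
    for (m in seq_along(resOrder)) {
      r <- resOrder[m]
      coords[.pIdx(r), ] <<- xyz[3 * m - 2, ]
      coords[.sIdx(r), ] <<- xyz[3 * m - 1, ]
      coords[.bIdx(r), ] <<- xyz[3 * m, ]
    }
    placed[resOrder] <<- TRUE
  }

  r <- 1L
  while (r <= n) {
    if (placed[r]) {
      ## resume after a placed block
      while (r <= n && placed[r]) r <- r + 1L
      if (r > n) break
      prev <- r - 1L
      pos <- coords[.sIdx(prev), ]
      d <- pos - coords[.pIdx(prev), ]
      nd <- sqrt(sum(d^2))
      dir <- if (nd > 1e-6) d / nd else dir
      next
    }
    if (helixOfS1[r] > 0L) {
      placeHelix(helixOfS1[r], pos, dir)
      next
    }
    ## unpaired run r..runEnd
    runEnd <- r
    while (runEnd < n && !placed[runEnd + 1L] && helixOfS1[runEnd + 1L] == 0L)
      runEnd <- runEnd + 1L
    anchored <- runEnd < n && placed[runEnd + 1L]
    resRun <- r:runEnd
    if (anchored) {
      A <- if (r == 1L) pos else coords[.sIdx(r - 1L), ]
      B <- coords[.pIdx(runEnd + 1L), ]
      npts <- 2L * length(resRun)
      perpSeed <- as.numeric(.rotAbout(c(0, 0, 1), 360 * rng()) %*% c(0, 1, 0))
      pts <- .arcPoints(A, B, npts, bond, perpSeed)
      for (m in seq_along(resRun)) {
        rr <- resRun[m]
        coords[.pIdx(rr), ] <- pts[2 * m - 1, ]
        coords[.sIdx(rr), ] <- pts[2 * m, ]
        off <- .unitPerp((B - A) / max(sqrt(sum((B - A)^2)), 1e-6))
        coords[.bIdx(rr), ] <- pts[2 * m, ] + off * ref$b_SB
      }
    } else {
      for (rr in resRun) {
        wig <- .rotAbout(.unitPerp(dir), 6 * (rng() - 0.5) * 10)
        dir <- as.numeric(wig %*% dir)
        pP <- pos + dir * bond
        pS <- pP + dir * bond
        perp <- .unitPerp(dir)
        coords[.pIdx(rr), ] <- pP + perp * 0.4
        coords[.sIdx(rr), ] <- pS
        coords[.bIdx(rr), ] <- pS + perp * ref$b_SB
        pos <- pS
      }
    }
    placed[resRun] <- TRUE
    r <- runEnd + 1L
  }
  ## steric filler beads at pair midpoints
  nc <- ss@pairs[ss@pairs$class == "noncanonical", , drop = FALSE]
  if (nrow(nc)) {
    for (k in seq_len(nrow(nc))) {
      mid <- (coords[.bIdx(nc$i[k]), ] + coords[.bIdx(nc$j[k]), ]) / 2
      coords[3L * n + k, ] <- mid + c(0.3, 0.2, 0.1)
    }
  }
  coords
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## staged relaxation: close the chain without sterics, then ramp sterics in
.relaxChain <- function(chain, coords, seed) {
  stage <- 0L
  run <- function(coords, ev, evScale, T, moves) {
    stage <<- stage + 1L
    sys <- .sysList(chain, ev = ev, evScale = evScale,
                    amplitudes = c(30, 25, 6, 0.6, 0.5))
    out <- .cppRemdRun(sys, coords, T, 1L, as.integer(moves), 0L,
                       integer(0), seed + 17 * stage, 1L)
    out$finalCoords[[1]]
  }
  nmv <- max(20000L, 120L * length(chain@ss@sequence))
  for (T in c(900, 400, 150)) coords <- run(coords, FALSE, 0, T, nmv)
  for (sc in c(0.25, 0.6, 1)) coords <- run(coords, TRUE, sc, 300, nmv)
  coords <- run(coords, TRUE, 1, 300, nmv %/% 2)
  coords
}

#' Build the coarse-grained chain for a secondary structure
#'
#' Creates the three-bead model: canonical helices become rigid ideal A-form
#' duplexes (one rigid group each), all other residues freely rotatable
#' chains; noncanonical pairs receive a steric filler bead, the weak
#' base-base attraction, quarter-strength backbone dihedrals and their fixed
#' internal flat-bottom restraints (B-B window 5.5-7.5 A, S-S window
#' 11-14 A). The initial conformation is laid out heuristically and relaxed
#' (without sterics first, then ramping the repulsion in) until the chain is
#' closed and overlap-free; with `init` coordinates the layout step is
#' skipped and helices are snapped onto their rigid templates.
#'
#' @param ss [SecondaryStructure-class]
#' @param ff [ForceFieldParams-class]
#' @param regions optional named region list ([readRegions()]); used to name
#'   helices and kept for analysis.
#' @param init optional bead coordinates (3*n x 3, P/S/B per residue) from
#'   [mapPdbToBeads()].
#' @param seed integer; layout/relaxation randomness is fully determined by
#'   it.
#' @param relax logical; relax the built conformation (default TRUE; an
#'   `init` conformation is relaxed only if it has steric overlap).
#' @param maxAttempts layout retries before giving up.
#' @return a [CoarseChain-class]
#' @export
buildChain <- function(ss, ff = forceFieldParams(), regions = list(),
                       init = NULL, seed = 1L, relax = TRUE,
                       maxAttempts = 5L) {
  validObject(ss)
  tg <- decomposeTopology(ss, regions)
  ref <- aformReference(ff)
  bt <- .beadTable(ss)
  n <- length(ss@sequence)
  nb <- nrow(bt$beads)
  gr <- .makeGroups(tg, ff)
  group <- integer(nb)
  for (k in seq_along(gr$groups)) group[gr$groups[[k]]] <- k
  terms <- .assembleTerms(ss, tg, ff, bt$beads, group, bt$b2Owner, ref)
  moves <- .moveTables(ss, bt$beads, group, bt$b2Owner, terms$bonds)
  chain <- new("CoarseChain", ss = ss, topology = tg, ff = ff,
               beads = bt$beads, coords = matrix(0, nb, 3), group = group,
               groups = gr$groups, templates = gr$templates, terms = terms,
               moves = moves,
               buildInfo = list(seed = as.integer(seed)))
  if (!is.null(init)) {
    if (nrow(init) != 3L * n)
      stop("init must provide P/S/B coordinates for all ", n, " residues")
    coords <- matrix(NA_real_, nb, 3)
    coords[seq_len(3L * n), ] <- as.matrix(init)
    nc <- ss@pairs[ss@pairs$class == "noncanonical", , drop = FALSE]
    for (k in seq_len(nrow(nc)))
      coords[3L * n + k, ] <- (coords[.bIdx(nc$i[k]), ] +
                               coords[.bIdx(nc$j[k]), ]) / 2 + 0.2
    ## snap rigid groups onto their exact templates
    for (nm in names(chain@groups)) {
      idx <- chain@groups[[nm]]
      coords[idx, ] <- .kabschFit(chain@templates[[nm]], coords[idx, ])
    }
    chain@coords <- coords
    sys <- .sysList(chain)
    ov <- .cppMaxOverlap(sys, coords)
    if (relax && ov > 0.7)
      chain@coords <- .relaxChain(chain, coords, seed)
    chain@buildInfo$overlap <- .cppMaxOverlap(sys, chain@coords)
    chain@buildInfo$strain <- .cppMaxStrain(sys, chain@coords)
    return(chain)
  }
  for (attempt in seq_len(maxAttempts)) {
    coords <- .layoutChain(ss, tg, gr$groups, gr$templates, ff, ref,
                           seed * 1000L + attempt)
    if (relax) coords <- .relaxChain(chain, coords, seed * 1000L + attempt)
    sys <- .sysList(chain)
    strain <- .cppMaxStrain(sys, coords)
    overlap <- .cppMaxOverlap(sys, coords)
    ## gates: bonds within thermal range of ideal, no penetration beyond
    ## ~25% of a bead diameter (the soft spheres tolerate grazing contact)
    if (!relax || (strain < 1.2 && overlap < 1.2)) {
      chain@coords <- coords
      chain@buildInfo$attempt <- attempt
      chain@buildInfo$strain <- strain
      chain@buildInfo$overlap <- overlap
      return(chain)
    }
  }
  stop(sprintf(paste0("chain assembly failed after %d attempts ",
                      "(last strain %.2f A, overlap %.2f A); the topology ",
                      "may be unsatisfiable with the current layout"),
               maxAttempts, strain, overlap))
}

.kabschFit <- function(tpl, cur) {
  cT <- colMeans(tpl); cC <- colMeans(cur)
  H <- t(sweep(tpl, 2, cT)) %*% sweep(cur, 2, cC)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(tpl, 2, cT) %*% t(R)
  sweep(out, 2, cC, "+")
}

## ---- PDB mapping --------------------------------------------------------

#' Map all-atom PDB coordinates onto P/S/B beads
#'
#' P bead from the P atom, S bead from C1' (or the configured anchor), B bead
#' from N9 (purines) / N1 (pyrimidines). A 5' terminal residue lacking its P
#' atom is imputed from O5' when available; unmappable beads are reported in
#' the gap report.
#'
#' @param pdb a `bio3d` pdb object or a path readable by [bio3d::read.pdb()]
#' @param ss [SecondaryStructure-class] whose numbering map aligns to PDB
#'   residue numbers
#' @param chain PDB chain identifier (default: first chain present)
#' @param sAnchor sugar anchor atom name (default "C1'")
#' @return list with `coords` (3n x 3 matrix) and `gaps` (data.frame of
#'   missing atoms)
#' @export
mapPdbToBeads <- function(pdb, ss, chain = NULL, sAnchor = "C1'") {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no atoms for chain ", chain)
  n <- length(ss@sequence)
  coords <- matrix(NA_real_, 3L * n, 3)
  gaps <- list()
  norm <- function(x) gsub("\\*", "'", x)
  at$elety <- norm(at$elety)
  for (r in seq_len(n)) {
    rows <- at[at$resno == ss@numbering[r], , drop = FALSE]
    if (!nrow(rows)) {
      gaps[[length(gaps) + 1L]] <- data.frame(residue = r, bead = "all",
                                              note = "residue absent")
      next
    }
    get <- function(name) {
      hit <- rows[rows$elety == name, , drop = FALSE]
      if (nrow(hit)) as.numeric(hit[1, c("x", "y", "z")]) else NULL
    }
    p <- get("P")
    if (is.null(p)) {
      p <- get("O5'")
      note <- if (!is.null(p)) "P imputed from O5'" else "P missing"
      gaps[[length(gaps) + 1L]] <- data.frame(residue = r, bead = "P",
                                              note = note)
    }
    s <- get(norm(sAnchor))
    bName <- if (ss@sequence[r] %in% c("A", "G")) "N9" else "N1"
    b <- get(bName)
    if (is.null(s))
      gaps[[length(gaps) + 1L]] <- data.frame(residue = r, bead = "S",
                                              note = "sugar anchor missing")
    if (is.null(b))
      gaps[[length(gaps) + 1L]] <- data.frame(residue = r, bead = "B",
                                              note = paste(bName, "missing"))
    if (!is.null(p)) coords[.pIdx(r), ] <- p
    if (!is.null(s)) coords[.sIdx(r), ] <- s
    if (!is.null(b)) coords[.bIdx(r), ] <- b
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps)
          else data.frame(residue = integer(), bead = character(),
                          note = character())
  list(coords = coords, gaps = gaps)
}

#' Write beads as a coarse-grained PDB file (pseudo-atoms P/S/B)
#' @param chain [CoarseChain-class]; @param file path
#' @param coords optional coordinates overriding the chain's
#' @export
writeCoarsePDB <- function(chain, file, coords = chain@coords) {
  ss <- chain@ss
  lines <- character(nrow(coords))
  for (k in seq_len(nrow(coords))) {
    r <- chain@beads$residue[k]
    nm <- chain@beads$type[k]
    lines[k] <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      k, nm, paste0("R", ss@sequence[r]), ss@numbering[r],
      coords[k, 1], coords[k, 2], coords[k, 3])
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Read a coarse-grained PDB written by [writeCoarsePDB()]
#' @param file path
#' @return list with `coords`, `resno`, `name`
#' @export
readCoarsePDB <- function(file) {
  lines <- readLines(file)
  lines <- lines[startsWith(lines, "ATOM")]
  coords <- cbind(as.numeric(substr(lines, 31, 38)),
                  as.numeric(substr(lines, 39, 46)),
                  as.numeric(substr(lines, 47, 54)))
  list(coords = coords,
       resno = as.integer(substr(lines, 23, 26)),
       name = trimws(substr(lines, 13, 16)))
}
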