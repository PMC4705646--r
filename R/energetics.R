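## Contact probabilities and the free-energy stack: dG_topo, ddG_coop,
## dG_fold, tetraloop/receptor matrices, residue-resolved maps, and the
## P4/P6 stacking proxy.

#' ContactDefinition: which bead distances define a contact
#'
#' A contact is formed in a frame when at least `minPairs` sugar-bead pairs
#' `(i in setI, j in setJ)` lie within `cutoff`. The 14 A default
#' corresponds roughly to the distance across a canonical base pair;
#' residue-residue contacts use `minPairs = 1`, tetraloop/receptor and
#' J6/P3 contacts use `minPairs = 2`.
#'
#' @slot setI,setJ disjoint residue sets (1-based positions)
#' @slot cutoff Angstrom; @slot minPairs integer
#' @exportClass ContactDefinition
setClass("ContactDefinition",
  representation(setI = "integer", setJ = "integer", cutoff = "numeric",
                 minPairs = "integer"))

setValidity("ContactDefinition", function(object) {
  if (length(intersect(object@setI, object@setJ)))
    return("contact residue sets must be disjoint")
  if (object@cutoff <= 0) return("cutoff must be positive")
  if (object@minPairs < 1) return("minPairs must be >= 1")
  TRUE
})

#' Create a contact definition
#' @param setI,setJ residue sets (1-based)
#' @param cutoff Angstrom (default 14)
#' @param minPairs minimum number of in-range S-bead pairs (default 1)
#' @export
contactDefinition <- function(setI, setJ, cutoff = 14, minPairs = 1) {
  new("ContactDefinition", setI = as.integer(setI), setJ = as.integer(setJ),
      cutoff = cutoff, minPairs = as.integer(minPairs))
}

#' Per-frame contact indicator for a contact definition
#' @param traj [TrajectoryEnsemble-class]; @param cdef
#'   [ContactDefinition-class]
#' @return logical vector over all recorded frames
#' @export
contactSeries <- function(traj, cdef) {
  rowsA <- traj@sRow[cdef@setI]; rowsB <- traj@sRow[cdef@setJ]
  if (any(is.na(rowsA)) || any(is.na(rowsB)))
    stop("contact residues not present in the recorded bead selection")
  sub <- c(rowsA, rowsB)
  fr <- .frames2d(traj, sub)
  cnt <- .cppContactCounts(fr, seq_along(rowsA),
                           length(rowsA) + seq_along(rowsB), cdef@cutoff)
  cnt >= cdef@minPairs
}

.blockBootstrap <- function(ind, blocks, resamples, seed) {
  n <- length(ind)
  blocks <- max(2L, min(blocks, n))
  edges <- floor(seq(0, n, length.out = blocks + 1))
  sums <- diff(cumsum(c(0, ind))[edges + 1])
  sizes <- diff(edges)
  oldseed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = .GlobalEnv))
  set.seed(seed)
  pick <- matrix(sample.int(blocks, blocks * resamples, replace = TRUE),
                 resamples, blocks)
  num <- matrix(sums[pick], resamples, blocks)
  den <- matrix(sizes[pick], resamples, blocks)
  rowSums(num) / rowSums(den)
}

#' Contact probability and dG_topo with block-bootstrap uncertainty
#'
#' The probability that the contact is formed over post-equilibration
#' frames (optionally masked by a per-frame condition), converted to the
#' conformational free energy `dG_topo = -RT ln(p / (1 - p))`. Uncertainty
#' comes from a seeded block bootstrap over contiguous frame blocks
#' (correlation-aware). When p is 0 or 1 the returned dG is a one-sided
#' bound from the pseudocount `1/(N + 1)` and is flagged as such.
#'
#' @param traj [TrajectoryEnsemble-class]
#' @param cdef [ContactDefinition-class]
#' @param condition optional logical vector over all recorded frames
#'   (e.g. a stacking-proxy mask); combined with the post-equilibration cut
#' @param temperature K (default 300)
#' @param blocks,resamples,seed block bootstrap settings
#' @param tag conditioning tag stored in the result
#' @return [FreeEnergyResult-class]
#' @export
contactProbability <- function(traj, cdef, condition = NULL,
                               temperature = 300, blocks = 50,
                               resamples = 1000, seed = 1,
                               tag = NULL) {
  keep <- postEquilIdx(traj)
  ind <- contactSeries(traj, cdef)[keep]
  if (!is.null(condition)) {
    cond <- condition[keep]
    ind <- ind[cond]
    if (!length(ind)) stop("no frames left after applying the condition")
  }
  n <- length(ind); nc <- sum(ind)
  p <- nc / n
  bound <- p <= 0 || p >= 1
  pEff <- if (p <= 0) 1 / (n + 1) else if (p >= 1) n / (n + 1) else p
  dG <- dgTopo(pEff, temperature)
  ps <- .blockBootstrap(as.numeric(ind), blocks, resamples, seed)
  ps <- pmin(pmax(ps, 1 / (n + 1)), n / (n + 1))
  ci <- unname(quantile(dgTopo(ps, temperature), c(0.025, 0.975)))
  if (is.null(tag))
    tag <- if (is.null(condition)) traj@meta$restraintKind %||% "unrestrained"
           else "proxy-conditioned"
  new("FreeEnergyResult", p = p, nFrames = as.integer(n),
      nContact = as.integer(nc), dG = dG, ci = ci, bound = bound,
      temperature = temperature, tag = tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conformational free energy of a contact from its probability
#'
#' `dG_topo = -RT ln(p / (1 - p))` with R = 1.9872e-3 kcal/(mol K);
#' antisymmetric about p = 0.5.
#' @param p probability in (0, 1) (vectorized)
#' @param temperature K (default 300)
#' @return kcal/mol
#' @export
dgTopo <- function(p, temperature = 300) {
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly inside (0, 1); a p of 0/1 signals an ",
         "unsampled or always-formed contact, use the pseudocount bound")
  -.RGAS * temperature * log(p / (1 - p))
}

#' Tertiary cooperativity: change in dG_topo under conditioning
#'
#' `ddG_coop(x, y) = dG_topo(x | y) - dG_topo(x)`; negative values mean the
#' conditioning interaction stabilizes contact x.
#' @param dgConditional,dgUnconditional kcal/mol
#' @export
ddgCoop <- function(dgConditional, dgUnconditional) {
  if (!all(is.finite(c(dgConditional, dgUnconditional))))
    stop("ddG_coop needs finite dG values (not bounds)")
  dgConditional - dgUnconditional
}

#' FoldEnergyParams: reference constants of the dG_fold transfer relation
#' @slot refFold experimental reference folding free energy (kcal/mol)
#' @slot refTopo simulated reference topological penalty (kcal/mol)
#' @exportClass FoldEnergyParams
setClass("FoldEnergyParams",
  representation(refFold = "numeric", refTopo = "numeric"))

setValidity("FoldEnergyParams", function(object) {
  if (!is.finite(object@refFold) || !is.finite(object@refTopo))
    return("reference energies must be finite")
  TRUE
})

#' Reference parameters for dG_fold
#' @param refFold experimental reference (default -0.3 kcal/mol)
#' @param refTopo simulated reference penalty (default 2.9 kcal/mol)
#' @export
foldEnergyParams <- function(refFold = -0.3, refTopo = 2.9)
  new("FoldEnergyParams", refFold = refFold, refTopo = refTopo)

#' Folding free energy by reference transfer
#'
#' `dG_fold = dG_fold_ref - dG_topo_ref + dG_topo`, assuming all
#' non-topological terms are constant across architectures.
#' @param dgTopoValue kcal/mol (vectorized)
#' @param params [FoldEnergyParams-class]
#' @export
dgFold <- function(dgTopoValue, params = foldEnergyParams()) {
  params@refFold - params@refTopo + dgTopoValue
}

#' dG_topo matrix over tetraloop/receptor combinations
#'
#' Full cross matrix of loops against receptors with `minPairs = 2` (a
#' single in-range residue pair is not yet a docked motif).
#' @param traj [TrajectoryEnsemble-class]
#' @param loops,receptors named lists of residue sets
#' @param native character vector of native combinations ("L2/J8" style)
#' @param cutoff,minPairs contact definition settings
#' @param condition,temperature,blocks,resamples,seed as in
#'   [contactProbability()]
#' @return data.frame: loop, receptor, p, dG, bound, ciLow, ciHigh, native, N
#' @export
tlTlrMatrix <- function(traj, loops, receptors, native = character(0),
                        cutoff = 14, minPairs = 2, condition = NULL,
                        temperature = 300, blocks = 50, resamples = 1000,
                        seed = 1) {
  out <- list()
  for (ln in names(loops)) for (rn in names(receptors)) {
    if (length(intersect(loops[[ln]], receptors[[rn]]))) next
    cdef <- contactDefinition(loops[[ln]], receptors[[rn]], cutoff, minPairs)
    fe <- contactProbability(traj, cdef, condition = condition,
                             temperature = temperature, blocks = blocks,
                             resamples = resamples, seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      loop = ln, receptor = rn, p = fe@p, dG = fe@dG, bound = fe@bound,
      ciLow = fe@ci[1], ciHigh = fe@ci[2],
      native = paste(ln, rn, sep = "/") %in% native, N = fe@nFrames)
  }
  do.call(rbind, out)
}

#' Residue-resolved dG_topo map for selected regions
#'
#' For each row region, the dG_topo of contacting every individual residue
#' (minPairs = 1), excluding residues inside the region itself.
#' @param traj [TrajectoryEnsemble-class]
#' @param rowRegions named list of residue sets
#' @param cutoff Angstrom; @param condition optional per-frame mask
#' @param temperature K
#' @param blocks,resamples,seed bootstrap settings
#' @return long data.frame: region, residue, numbering, p, dG, bound,
#'   ciLow, ciHigh, N
#' @export
pairwiseDgMap <- function(traj, rowRegions, cutoff = 14, condition = NULL,
                          temperature = 300, blocks = 50, resamples = 1000,
                          seed = 1) {
  keep <- postEquilIdx(traj)
  numbering <- traj@meta$numbering %||% seq_along(traj@sRow)
  fr <- .frames2d(traj)
  out <- list()
  for (rg in names(rowRegions)) {
    rowsA <- traj@sRow[rowRegions[[rg]]]
    if (any(is.na(rowsA))) stop("region not in recorded selection: ", rg)
    cnt <- .cppRegionContact(fr, rowsA, cutoff)  # frames x beads
    for (res in seq_along(traj@sRow)) {
      if (res %in% rowRegions[[rg]]) next
      col <- traj@sRow[res]
      if (is.na(col)) next
      ind <- (cnt[keep, col] >= 1)
      if (!is.null(condition)) ind <- ind[condition[keep]]
      n <- length(ind); nc <- sum(ind); p <- nc / n
      bound <- p <= 0 || p >= 1
      pEff <- min(max(p, 1 / (n + 1)), n / (n + 1))
      ps <- .blockBootstrap(as.numeric(ind), blocks, resamples,
                            seed + res)
      ps <- pmin(pmax(ps, 1 / (n + 1)), n / (n + 1))
      ci <- unname(quantile(dgTopo(ps, temperature), c(0.025, 0.975)))
      out[[length(out) + 1L]] <- data.frame(
        region = rg, residue = res, numbering = numbering[res], p = p,
        dG = dgTopo(pEff, temperature), bound = bound, ciLow = ci[1],
        ciHigh = ci[2], N = n)
    }
  }
  do.call(rbind, out)
}

#' Detect P4/P6 coaxial stacking (triple-helix proxy)
#'
#' A frame counts as stacked when the interhelical bend between the two
#' helices exceeds `betaMin` (the frames of directly bonded stacked helices
#' are antiparallel in this convention, so a coaxial stack has beta near
#' 180 degrees) and the facing helix-end sugar-bead centroids are closer
#' than `gapMax`.
#'
#' @param traj [TrajectoryEnsemble-class]
#' @param helixA,helixB helix names (default P4, P6)
#' @param betaMin degrees (default 150)
#' @param gapMax Angstrom (default 7)
#' @return logical vector over all recorded frames
#' @export
detectP4P6Stacking <- function(traj, helixA = "P4", helixB = "P6",
                               betaMin = 150, gapMax = 7) {
  ha <- traj@helices[[helixA]]; hb <- traj@helices[[helixB]]
  if (is.null(ha) || is.null(hb)) stop("helices not defined in trajectory")
  ## facing ends: the base pairs whose residues are closest in sequence
  ## across the junction between the two helices
  pairsOf <- function(h) {
    nbp <- length(h$res1)
    cbind(h$res1, rev(h$res2))
  }
  pa <- pairsOf(ha); pb <- pairsOf(hb)
  gap <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(i, j) {
    pmin(abs(pa[i, 1] - pb[j, 1]), abs(pa[i, 1] - pb[j, 2]),
         abs(pa[i, 2] - pb[j, 1]), abs(pa[i, 2] - pb[j, 2]))
  })
  best <- which(gap == min(gap), arr.ind = TRUE)[1, ]
  endA <- pa[best[1], ]; endB <- pb[best[2], ]
  rowsA <- traj@sRow[endA]; rowsB <- traj@sRow[endB]
  centroid <- function(rows) {
    (traj@frames[, rows[1], ] + traj@frames[, rows[2], ]) / 2
  }
  cA <- centroid(rowsA); cB <- centroid(rowsB)
  gapDist <- sqrt(rowSums((cA - cB)^2))
  es <- eulerSeries(traj, helixA, helixB, frames = seq_len(dim(traj@frames)[1]))
  beta <- es@angles[, 2]
  beta > betaMin & gapDist < gapMax
}

#' Freely-jointed-chain estimate of the pivot-count free-energy difference
#'
#' For two connection paths with `nA` and `nB` flexible pivots, the
#' Gaussian-chain contact-probability ratio gives
#' `ddG = -RT (3/2) ln(nB / nA)`: the path with fewer pivots is favored.
#' @param nPivotsA,nPivotsB pivot counts (>= 1)
#' @param temperature K (default 300)
#' @return kcal/mol (negative when nA < nB)
#' @export
fjcPivotPenalty <- function(nPivotsA, nPivotsB, temperature = 300) {
  if (any(c(nPivotsA, nPivotsB) < 1)) stop("pivot counts must be >= 1")
  -.RGAS * temperature * 1.5 * log(nPivotsB / nPivotsA)
}
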