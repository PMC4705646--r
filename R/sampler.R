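## Monte Carlo sampling with temperature replica exchange, and the basic
## geometric observables (radius of gyration, P-bead RMSD).

#' Exponentially spaced temperature ladder
#' @param tmin,tmax ladder ends in K; @param n rung count
#' @export
tempLadder <- function(tmin = 300, tmax = 400, n = 8) {
  tmin * (tmax / tmin)^((seq_len(n) - 1) / (n - 1))
}

#' Sampler configuration
#'
#' Defaults follow the study conditions: eight exponentially spaced
#' temperatures spanning 300-400 K with neighbour exchanges attempted every
#' `exchangeEvery` moves, frames recorded from whichever replica currently
#' holds the analysis temperature (the lowest rung), and the first
#' `equilFrac` of recorded frames marked as equilibration. "Moves" are Monte
#' Carlo proposals; see the methods vignette for how move counts relate to
#' sampling effort.
#'
#' @param temps temperature ladder (K)
#' @param exchangeEvery moves between exchange attempts
#' @param totalMoves total moves per replica
#' @param recordEvery record interval (moves) within the analysis-temperature
#'   replica
#' @param seed RNG seed; every stochastic output records it
#' @param equilFrac fraction of frames marked equilibration (default 1%)
#' @param moveWeights proposal weights (pivot, segment, helix, local)
#' @param amplitudes max amplitudes: pivot/segment/helix rotations (deg),
#'   helix translation (A), local displacement (A)
#' @param record bead selection stored per frame: "S", "PS" or "all"
#' @param ev,angles toggles for sterics and backbone bending terms
#' @return [SamplerConfig-class]
#' @export
samplerConfig <- function(temps = tempLadder(), exchangeEvery = 500,
                          totalMoves = 200000, recordEvery = 10, seed = 1,
                          equilFrac = 0.01,
                          moveWeights = c(pivot = 0.3, segment = 0.25,
                                          helix = 0.15, local = 0.3),
                          amplitudes = c(pivot = 180, segment = 60,
                                         helix = 3, helixTrans = 0.35,
                                         local = 0.6),
                          record = c("S", "PS", "all"), ev = TRUE,
                          angles = TRUE) {
  record <- match.arg(record)
  new("SamplerConfig", temps = as.numeric(temps),
      exchangeEvery = as.integer(exchangeEvery),
      totalMoves = as.integer(totalMoves),
      recordEvery = as.integer(recordEvery), seed = as.integer(seed),
      equilFrac = equilFrac, moveWeights = moveWeights,
      amplitudes = amplitudes,
      options = list(record = record, ev = ev, angles = angles))
}

#' Total energy with per-term breakdown
#'
#' @param chain [CoarseChain-class]
#' @param conformation coordinates (default: the chain's current ones)
#' @param restraints optional [RestraintSet-class]
#' @param ev,angles term toggles
#' @return named numeric vector (kcal/mol): bond, angle, dihedral, ev,
#'   attraction, noe, dihres, rg, total
#' @export
chainEnergy <- function(chain, conformation = chain@coords,
                        restraints = NULL, ev = TRUE, angles = TRUE) {
  sys <- .sysList(chain, restraints = restraints, ev = ev, angles = angles)
  .cppEnergy(sys, as.matrix(conformation))
}

#' Run replica-exchange Monte Carlo
#'
#' Samples the Boltzmann distribution of the chain (plus any restraints)
#' with Metropolis Monte Carlo at each rung of the temperature ladder and
#' neighbour exchanges (even/odd alternating sweeps) with acceptance
#' `min(1, exp[(beta_i - beta_j)(E_i - E_j)])`. Frames are recorded from the
#' replica currently at the analysis temperature. Rigid helix groups are
#' exactly preserved: proposals never split a rigid group, and groups are
#' re-snapped onto their templates at every energy resync so floating-point
#' drift cannot accumulate.
#'
#' @param chain [CoarseChain-class]
#' @param restraints optional [RestraintSet-class]
#' @param config [SamplerConfig-class]
#' @param startCoords optional starting conformation (default: the chain's)
#' @return [TrajectoryEnsemble-class]
#' @export
remdRun <- function(chain, restraints = NULL, config = samplerConfig(),
                    startCoords = NULL) {
  validObject(config)
  n <- length(chain@ss@sequence)
  sel <- switch(config@options$record,
                S = .sIdx(1:n),
                PS = as.integer(rbind(.pIdx(1:n), .sIdx(1:n))),
                all = seq_len(nrow(chain@beads)))
  sys <- .sysList(chain, restraints = restraints,
                  ev = config@options$ev, angles = config@options$angles,
                  weights = unname(config@moveWeights),
                  amplitudes = unname(config@amplitudes))
  rounds <- config@totalMoves %/% config@exchangeEvery
  X0 <- if (is.null(startCoords)) chain@coords else as.matrix(startCoords)
  t0 <- proc.time()[3]
  out <- .cppRemdRun(sys, X0, config@temps, rounds, config@exchangeEvery,
                     config@recordEvery, sel, config@seed, 10L)
  elapsed <- proc.time()[3] - t0
  nF <- out$nFrames
  fr <- out$frames[seq_len(nF), , drop = FALSE]
  frames <- aperm(array(t(fr), dim = c(3, length(sel), nF)), c(3, 2, 1))
  sRow <- match(.sIdx(1:n), sel)
  pRow <- match(.pIdx(1:n), sel)
  helixMeta <- .helixMeta(chain, sRow)
  nT <- length(config@temps)
  exch <- data.frame(pair = if (nT > 1)
                       paste(seq_len(nT - 1), seq(2, nT), sep = "-")
                     else character(0),
                     attempts = if (nT > 1) out$exchAtt else integer(0),
                     accepts = if (nT > 1) out$exchAcc else integer(0))
  if (nrow(exch)) exch$rate <- ifelse(exch$attempts > 0,
                                      exch$accepts / exch$attempts, NA)
  new("TrajectoryEnsemble", frames = frames, selection = as.integer(sel),
      sRow = as.integer(sRow), pRow = as.integer(pRow),
      rg = out$rg[seq_len(nF)], step = out$step[seq_len(nF)],
      replica = out$replica[seq_len(nF)], helices = helixMeta,
      config = config, exchange = exch,
      equilFrames = as.integer(floor(config@equilFrac * nF)),
      meta = list(record = config@options$record,
                  restraintKind = if (is.null(restraints)) "unrestrained"
                                  else restraints@kind,
                  moveAccept = out$moveAcc / pmax(out$moveAtt, 1),
                  finalE = out$finalE, seconds = elapsed,
                  numbering = chain@ss@numbering,
                  sequence = chain@ss@sequence))
}

.helixMeta <- function(chain, sRow) {
  h <- chain@topology@helices
  out <- list()
  for (k in seq_len(nrow(h))) {
    if (h$n_bp[k] < 2) next
    s1 <- seq(h$s1_start[k], h$s1_end[k])
    s2 <- seq(h$s2_start[k], h$s2_end[k])
    tpl <- chain@templates[[h$name[k]]]
    nbp <- h$n_bp[k]
    tplS <- tpl[3 * seq_len(2 * nbp) - 1, , drop = FALSE]
    rows <- sRow[c(s1, s2)]
    if (any(is.na(rows))) next
    out[[h$name[k]]] <- list(name = h$name[k], res1 = s1, res2 = s2,
                             tplS = tplS, rows = rows)
  }
  out
}

#' Indices of post-equilibration frames
#' @param traj [TrajectoryEnsemble-class]
#' @export
postEquilIdx <- function(traj) {
  nF <- dim(traj@frames)[1]
  if (traj@equilFrames >= nF) stop("no frames after the equilibration cut")
  seq(traj@equilFrames + 1L, nF)
}

#' Radius of gyration
#'
#' For a coordinate matrix: the mass-uniform Rg of the selected rows. For a
#' trajectory: the per-frame all-bead Rg recorded during the run.
#' @param x matrix or [TrajectoryEnsemble-class]
#' @param selection optional row indices (matrix input)
#' @return numeric (scalar for a matrix, per-frame vector for a trajectory)
#' @export
radiusOfGyration <- function(x, selection = NULL) {
  if (is(x, "TrajectoryEnsemble")) return(x@rg)
  m <- as.matrix(x)
  if (!is.null(selection)) m <- m[selection, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least two beads for Rg")
  ctr <- colMeans(m)
  sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
}

#' Least-squares superposition RMSD over P beads
#'
#' @param frame,reference coordinate matrices covering the same beads
#'   (full bead sets; P rows are extracted via `chain`), or matrices of
#'   P-bead coordinates when `chain` is NULL
#' @param chain optional [CoarseChain-class]
#' @return RMSD in Angstrom after optimal superposition
#' @export
rmsdPBeads <- function(frame, reference, chain = NULL) {
  if (!is.null(chain)) {
    pidx <- which(chain@beads$type == "P")
    frame <- frame[pidx, , drop = FALSE]
    reference <- reference[pidx, , drop = FALSE]
  }
  if (nrow(frame) != nrow(reference)) stop("P-bead counts differ")
  .cppKabschRmsd(as.matrix(frame), as.matrix(reference))
}

#' Superposition RMSD of two point sets (Kabsch)
#' @param A,B n x 3 matrices
#' @export
kabschRmsd <- function(A, B) .cppKabschRmsd(as.matrix(A), as.matrix(B))

## ---- trajectory text serialization -------------------------------------

#' Write a trajectory as a plain-text table
#'
#' Long-format TSV (`frame`, `row`, `x`, `y`, `z`) preceded by headers with
#' the selection, per-frame Rg/step/replica and the seed, so the file
#' round-trips through [readTrajectoryTSV()].
#' @param traj [TrajectoryEnsemble-class]; @param file path
#' @export
writeTrajectoryTSV <- function(traj, file) {
  con <- file(file, "w"); on.exit(close(con))
  d <- dim(traj@frames)
  writeLines(sprintf("# rnatopo trajectory: %d frames x %d beads", d[1], d[2]),
             con)
  writeLines(sprintf("# seed: %d", traj@config@seed), con)
  writeLines(sprintf("# selection: %s",
                     paste(traj@selection, collapse = ",")), con)
  writeLines(sprintf("# rg: %s",
                     paste(formatC(traj@rg, format = "g", digits = 8),
                           collapse = ",")), con)
  writeLines("frame\trow\tx\ty\tz", con)
  for (f in seq_len(d[1])) {
    m <- traj@frames[f, , , drop = TRUE]
    writeLines(sprintf("%d\t%d\t%.4f\t%.4f\t%.4f", f, seq_len(d[2]),
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(file)
}

#' Read a trajectory written by [writeTrajectoryTSV()]
#' @param file path
#' @return list with `frames` array, `selection`, `rg`, `seed`
#' @export
readTrajectoryTSV <- function(file) {
  hdr <- .readHeaders(file)
  tab <- read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  nF <- max(tab$frame); nb <- max(tab$row)
  frames <- array(NA_real_, c(nF, nb, 3))
  idx <- cbind(tab$frame, tab$row)
  frames[cbind(idx, 1L)] <- tab$x
  frames[cbind(idx, 2L)] <- tab$y
  frames[cbind(idx, 3L)] <- tab$z
  list(frames = frames,
       selection = as.integer(strsplit(hdr$selection, ",")[[1]]),
       rg = as.numeric(strsplit(hdr$rg, ",")[[1]]),
       seed = as.integer(hdr$seed))
}
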