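## Statistically controlled synthetic ensembles. Every generator is
## deterministic under its seed and embeds its ground truth in the
## trajectory metadata so tests check against the enforced statistic, never
## a re-derived one.

.minimalConfig <- function(seed, temps = 300) {
  samplerConfig(temps = temps, exchangeEvery = 1, totalMoves = 1,
                recordEvery = 1, seed = seed, equilFrac = 0)
}

.syntheticTraj <- function(frames, seed, groundTruth, rg = numeric(0)) {
  nF <- dim(frames)[1]; nbead <- dim(frames)[2]
  if (!length(rg))
    rg <- vapply(seq_len(nF), function(f)
      radiusOfGyration(frames[f, , , drop = TRUE]), numeric(1))
  new("TrajectoryEnsemble", frames = frames,
      selection = seq_len(nbead), sRow = seq_len(nbead),
      pRow = rep(NA_integer_, nbead), rg = rg,
      step = seq_len(nF), replica = rep(1L, nF), helices = list(),
      config = .minimalConfig(seed), exchange = data.frame(),
      equilFrames = 0L,
      meta = c(groundTruth, list(record = "synthetic", seed = seed)))
}

.localSeed <- function(seed, expr) {
  oldseed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Ideal freely-jointed chain ensemble (no sterics)
#'
#' Frames are i.i.d. random-direction chains of `nLinks` rigid links; the
#' enforced ground truth is the closed form `<R_ee^2> = nLinks * b^2`,
#' recorded in the metadata.
#' @param nLinks number of links (>= 1)
#' @param bondLength b in Angstrom
#' @param nFrames frames to draw
#' @param seed integer
#' @return [TrajectoryEnsemble-class] over `nLinks + 1` beads
#' @export
genIdealChain <- function(nLinks, bondLength = 5.36, nFrames = 1000,
                          seed = 1) {
  if (nLinks < 1) stop("need at least one link")
  frames <- .localSeed(seed, {
    out <- array(0, c(nFrames, nLinks + 1L, 3))
    for (f in seq_len(nFrames)) {
      v <- matrix(rnorm(3 * nLinks), nLinks, 3)
      v <- v / sqrt(rowSums(v^2)) * bondLength
      out[f, , ] <- rbind(0, apply(v, 2, cumsum))
    }
    out
  })
  .syntheticTraj(frames, seed,
                 list(generator = "ideal_chain", nLinks = nLinks,
                      bondLength = bondLength,
                      meanRee2 = nLinks * bondLength^2))
}

#' End-to-end squared distances of a chain ensemble
#' @param traj [TrajectoryEnsemble-class]
#' @export
endToEndSq <- function(traj) {
  nb <- dim(traj@frames)[2]
  rowSums((traj@frames[, nb, ] - traj@frames[, 1, ])^2)
}

.randomRotations <- function(n) {
  ## uniform over SO(3) via normalized quaternions
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

.rotToEuler <- function(R) {
  ## R is n x 9 row-major
  .eulerFromRel(R[, 1], R[, 4], R[, 3], R[, 6], R[, 7], R[, 8], R[, 9])
}

#' Correlated pair of orientation series
#'
#' `correlation = 0` gives two independent uniform rotation series;
#' `correlation = 1` two identical series; intermediate values perturb the
#' first series by a random rotation whose angle shrinks as the correlation
#' parameter grows (ground truth: estimated MI is monotone in the
#' parameter).
#' @param correlation in `[0, 1]`
#' @param n series length
#' @param seed integer
#' @return list of two [EulerSeries-class]
#' @export
genRotationPair <- function(correlation, n, seed = 1) {
  if (correlation < 0 || correlation > 1)
    stop("correlation must lie in [0, 1]")
  .localSeed(seed, {
    R1 <- .randomRotations(n)
    R2 <- if (correlation >= 1) R1
    else if (correlation <= 0) .randomRotations(n)
    else {
      ## perturb by a rotation with concentrated random angle
      ang <- rnorm(n, 0, (1 - correlation) * pi / 2)
      ax <- matrix(rnorm(3 * n), n, 3)
      ax <- ax / sqrt(rowSums(ax^2))
      out <- matrix(0, n, 9)
      for (k in seq_len(n)) {
        P <- .rotAbout(ax[k, ], ang[k] * 180 / pi)
        M <- P %*% matrix(R1[k, ], 3, 3, byrow = TRUE)
        out[k, ] <- as.numeric(t(M))
      }
      out
    }
    mk <- function(R, tag) new("EulerSeries", angles = .rotToEuler(R),
                               pair = c("ref", tag),
                               frames = seq_len(n),
                               meta = list(generator = "rotation_pair",
                                           correlation = correlation,
                                           seed = seed))
    list(mk(R1, "X"), mk(R2, "Y"))
  })
}

#' Bead ensemble with prescribed contact probability
#'
#' Two sugar beads whose distance is inside the cutoff with exact Bernoulli
#' probability `pTarget` per independent frame (in-contact distances are
#' drawn inside the cutoff, out-of-contact outside it). The realized draw
#' count is recorded: the empirical frequency equals the Bernoulli draws by
#' construction.
#' @param pTarget in (0, 1)
#' @param nFrames independent frames
#' @param seed integer
#' @param cutoff Angstrom (default 14)
#' @return list with `traj` ([TrajectoryEnsemble-class]) and `cdef`
#'   ([ContactDefinition-class])
#' @export
genContactEnsemble <- function(pTarget, nFrames, seed = 1, cutoff = 14) {
  if (pTarget <= 0 || pTarget >= 1) stop("pTarget must be in (0, 1)")
  res <- .localSeed(seed, {
    contact <- runif(nFrames) < pTarget
    d <- ifelse(contact, runif(nFrames, 4, cutoff - 0.2),
                runif(nFrames, cutoff + 0.2, 3 * cutoff))
    dirs <- matrix(rnorm(3 * nFrames), nFrames, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    frames <- array(0, c(nFrames, 2L, 3))
    frames[, 2, ] <- dirs * d
    list(frames = frames, contact = contact)
  })
  traj <- .syntheticTraj(res$frames, seed,
                         list(generator = "contact_ensemble",
                              pTarget = pTarget, nContact = sum(res$contact),
                              cutoff = cutoff))
  list(traj = traj, cdef = contactDefinition(1L, 2L, cutoff, 1L))
}
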