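## Interhelical Euler angles and fraction-of-conformational-space analysis.
##
## Convention (fixed and documented; see the methods vignette): each helix
## carries a body frame with z along the helix axis oriented 5'->3' of the
## reference strand and x towards the reference 5' sugar bead projected
## perpendicular to z. The angles (alpha_h, beta_h, gamma_h) are the ZYZ
## decomposition of the rotation taking frame A into frame B; alpha/gamma
## are helix twists, beta the interhelical bend. Occupied-bin fractions and
## mutual information are invariant to the frame convention (a relabelling
## of bins); absolute angle values are not.

#' HelixFrame: origin plus right-handed orthonormal axes
#' @slot origin numeric(3); @slot axes 3x3 matrix (columns x, y, z)
#' @slot helix helix name; @slot referenceStrand 1 or 2
#' @exportClass HelixFrame
setClass("HelixFrame",
  representation(origin = "numeric", axes = "matrix", helix = "character",
                 referenceStrand = "integer"))

setValidity("HelixFrame", function(object) {
  A <- object@axes
  if (max(abs(t(A) %*% A - diag(3))) > 1e-9)
    return("axes must be orthonormal to 1e-9")
  if (det(A) < 0) return("axes must be right-handed (det +1)")
  TRUE
})

.frames2d <- function(traj, beads = NULL) {
  d <- dim(traj@frames)
  if (is.null(beads)) beads <- seq_len(d[2])
  m <- matrix(0, d[1], 3L * length(beads))
  for (dd in 1:3)
    m[, 3L * (seq_along(beads) - 1L) + dd] <- traj@frames[, beads, dd]
  m
}

#' Per-frame body frame of a helix
#'
#' Fits the rigid template of the helix to each recorded frame (exact for
#' rigid groups) and returns the per-frame rotation matrices and origins.
#' The template frame is the identity (z = axis, x = towards the reference
#' 5' sugar), so the fitted rotation *is* the frame.
#'
#' @param traj [TrajectoryEnsemble-class]
#' @param helix helix name present in the trajectory metadata
#' @return list with `rot` (n x 9 row-major rotation matrices) and `origin`
#'   (n x 3)
#' @export
helixFrames <- function(traj, helix) {
  hm <- traj@helices[[helix]]
  if (is.null(hm))
    stop("helix not available in trajectory (needs >= 2 base pairs): ", helix)
  fr <- .frames2d(traj, hm$rows)
  .cppFitFrames(fr, hm$tplS, seq_along(hm$rows))
}

#' Body frame of a helix in a single conformation
#'
#' @param chain [CoarseChain-class]
#' @param helix helix name
#' @param coords conformation (default the chain's)
#' @param referenceStrand 1 (default) or 2: strand whose 5'->3' direction
#'   orients the axis
#' @return [HelixFrame-class]
#' @export
helixFrame <- function(chain, helix, coords = chain@coords,
                       referenceStrand = 1L) {
  h <- chain@topology@helices
  k <- match(helix, h$name)
  if (is.na(k)) stop("unknown helix: ", helix)
  if (h$n_bp[k] < 2) stop("helix axis undefined for a 1-bp helix")
  idx <- chain@groups[[helix]]
  tpl <- chain@templates[[helix]]
  cur <- coords[idx, , drop = FALSE]
  fit <- .cppFitFrames(matrix(t(cur), nrow = 1), tpl, seq_len(nrow(tpl)))
  R <- matrix(fit$rot[1, ], 3, 3, byrow = TRUE)
  axes <- R
  if (referenceStrand == 2L) {
    ## flip: z reverses, x towards strand-2 5' sugar; keep right-handedness
    axes <- axes %*% diag(c(1, -1, -1))
  }
  new("HelixFrame", origin = as.numeric(fit$origin[1, ]), axes = axes,
      helix = helix, referenceStrand = as.integer(referenceStrand))
}

.eulerFromRel <- function(r11, r21, r13, r23, r31, r32, r33) {
  beta <- acos(pmin(1, pmax(-1, r33)))
  sb <- sin(beta)
  alpha <- atan2(r23, r13)
  gamma <- atan2(r32, -r31)
  gim <- sb < 1e-7
  if (any(gim)) {
    ## gimbal: assign all rotation to alpha, gamma := 0
    up <- gim & r33 > 0
    dn <- gim & r33 <= 0
    alpha[up] <- atan2(r21[up], r11[up])
    alpha[dn] <- atan2(-r21[dn], -r11[dn])
    gamma[gim] <- 0
  }
  deg <- cbind(alpha, beta, gamma) * 180 / pi
  deg[deg[, 1] >= 180, 1] <- -180
  deg[deg[, 3] >= 180, 3] <- -180
  colnames(deg) <- c("alpha", "beta", "gamma")
  deg
}

#' Euler angles between two helix frames
#'
#' ZYZ decomposition of the relative rotation taking frame A into frame B,
#' in degrees. At the gimbal singularities (beta = 0 or 180) gamma is set to
#' 0 and the full twist assigned to alpha.
#' @param frameA,frameB [HelixFrame-class] objects or 3x3 rotation matrices
#' @return numeric(3): alpha, beta, gamma
#' @export
eulerAngles <- function(frameA, frameB) {
  A <- if (is(frameA, "HelixFrame")) frameA@axes else frameA
  B <- if (is(frameB, "HelixFrame")) frameB@axes else frameB
  R <- t(A) %*% B
  out <- .eulerFromRel(R[1, 1], R[2, 1], R[1, 3], R[2, 3], R[3, 1], R[3, 2],
                       R[3, 3])
  setNames(as.numeric(out[1, ]), c("alpha", "beta", "gamma"))
}

#' Recompose the rotation matrix from ZYZ Euler angles (degrees)
#' @param alpha,beta,gamma degrees
#' @export
recomposeEuler <- function(alpha, beta, gamma) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Per-frame interhelical Euler angles for a helix pair
#'
#' @param traj [TrajectoryEnsemble-class]
#' @param helixA,helixB helix names (frame A is the first)
#' @param frames frame indices (default: post-equilibration frames)
#' @return [EulerSeries-class]
#' @export
eulerSeries <- function(traj, helixA, helixB, frames = postEquilIdx(traj)) {
  fa <- helixFrames(traj, helixA)
  fb <- helixFrames(traj, helixB)
  A <- fa$rot[frames, , drop = FALSE]
  B <- fb$rot[frames, , drop = FALSE]
  ## relative rotation elements of t(A) %*% B, rot stored row-major:
  ## col index of R[a,b] is 3*(a-1)+b
  el <- function(M, a, b) M[, 3L * (a - 1L) + b]
  rel <- function(i, j) {  # sum_k A[k,i] * B[k,j]
    el(A, 1, i) * el(B, 1, j) + el(A, 2, i) * el(B, 2, j) +
      el(A, 3, i) * el(B, 3, j)
  }
  ang <- .eulerFromRel(rel(1, 1), rel(2, 1), rel(1, 3), rel(2, 3),
                       rel(3, 1), rel(3, 2), rel(3, 3))
  new("EulerSeries", angles = ang, pair = c(helixA, helixB),
      frames = as.integer(frames), meta = list(convention = "ZYZ"))
}

## bin index triples; edges start at -180 (alpha, gamma) and 0 (beta); a
## sample exactly on an edge belongs to the higher bin
.eulerBins <- function(angles, w) {
  if (abs(360 / w - round(360 / w)) > 1e-9 ||
      abs(180 / w - round(180 / w)) > 1e-9)
    stop("bin width must divide 360 and 180 evenly")
  na <- as.integer(round(360 / w)); nb <- as.integer(round(180 / w))
  ia <- pmin(floor((angles[, 1] + 180) / w), na - 1)
  ib <- pmin(floor(angles[, 2] / w), nb - 1)
  ig <- pmin(floor((angles[, 3] + 180) / w), na - 1)
  list(id = (ia * nb + ib) * na + ig, nCells = as.numeric(na) * nb * na)
}

#' Fraction of orientation space sampled by a helix pair
#'
#' Occupied-bin count over total bin count on the (alpha, beta, gamma) grid;
#' with the default 10-degree bins the grid has 36 x 18 x 36 = 23328 cells.
#' No Jacobian correction is applied: the statistic is the raw occupied-bin
#' fraction.
#' @param series [EulerSeries-class]
#' @param binWidth degrees (must divide 360 and 180)
#' @return fraction in (0, 1]
#' @export
fractionSampled <- function(series, binWidth = 10) {
  a <- series@angles
  if (!nrow(a)) stop("empty Euler series")
  b <- .eulerBins(a, binWidth)
  length(unique(b$id)) / b$nCells
}

#' Fraction of joint k x (alpha, beta, gamma) conformations sampled
#'
#' For k aligned Euler series (the helix pairs of a junction), counts
#' occupied joint bins over `(bins per pair)^k`. With 30-degree bins and
#' k = 2 the denominator is 746496; with 60-degree bins and k = 3 it is
#' 1259712.
#' @param seriesList list of [EulerSeries-class] over common frames
#' @param binWidth degrees
#' @return joint fraction
#' @export
fractionJoint <- function(seriesList, binWidth = 30) {
  if (!length(seriesList)) stop("need at least one series")
  fr <- seriesList[[1]]@frames
  for (s in seriesList)
    if (!identical(s@frames, fr)) stop("series are not frame-aligned")
  ids <- lapply(seriesList, function(s) .eulerBins(s@angles, binWidth))
  nCells <- ids[[1]]$nCells
  key <- ids[[1]]$id
  if (length(ids) > 1)
    for (k in 2:length(ids)) key <- key * nCells + ids[[k]]$id
  length(unique(key)) / nCells^length(ids)
}

#' Normalized fraction of conformational space
#'
#' Computes `F*_samp` with 60-degree bins on a random subsample sized to
#' match a reference sampling density (conformations per bin), then
#' normalizes by the reference molecule's fraction `F_trna`. The reference
#' density follows the four-way-junction convention: 499000 conformations
#' over 108^3 joint bins; a k-pair junction is subsampled to
#' `ceiling(499000 * 108^k / 108^3)` conformations (4621 for k = 2).
#'
#' @param seriesList list of k aligned [EulerSeries-class]
#' @param fTrna reference fraction; no default (the value comes from the
#'   reference tRNA study and must be supplied)
#' @param seed subsample seed (logged in the result)
#' @param refConf,refBins reference density definition
#' @return list: `fNorm`, `fStar`, `nConf`, `seed`
#' @export
fractionNorm <- function(seriesList, fTrna = NULL, seed = 1,
                         refConf = 499000, refBins = 108^3) {
  if (is.null(fTrna))
    stop("fTrna must be supplied (the reference-molecule fraction is an ",
         "external input, not a package default)")
  k <- length(seriesList)
  nSub <- ceiling(refConf * 108^k / refBins)
  n <- nrow(seriesList[[1]]@angles)
  if (n < nSub)
    stop(sprintf("conformational pool (%d) smaller than required subsample (%d)",
                 n, nSub))
  oldseed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = .GlobalEnv))
  set.seed(seed)
  pick <- sort(sample.int(n, nSub))
  sub <- lapply(seriesList, function(s)
    new("EulerSeries", angles = s@angles[pick, , drop = FALSE],
        pair = s@pair, frames = s@frames[pick], meta = s@meta))
  fStar <- fractionJoint(sub, 60)
  list(fNorm = fStar / fTrna, fStar = fStar, nConf = nSub, seed = seed)
}

#' Export an Euler series as TSV (frame, alpha, beta, gamma)
#' @param series [EulerSeries-class]; @param file path
#' @export
writeEulerTSV <- function(series, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("# helix pair: %s %s", series@pair[1], series@pair[2]),
             con)
  writeLines("frame\talpha\tbeta\tgamma", con)
  a <- series@angles
  writeLines(sprintf("%d\t%.3f\t%.3f\t%.3f", series@frames, a[, 1], a[, 2],
                     a[, 3]), con)
  invisible(file)
}
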