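## Ideal A-form duplex template and derived reference geometry.

.cyl <- function(r, phiDeg, z) {
  a <- phiDeg * pi / 180
  c(r * cos(a), r * sin(a), z)
}

.rotz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Build an ideal A-form duplex for a run of consecutive pairs
#'
#' Generates the rigid-body bead geometry of an idealized A-form helix from
#' fiber-type parameters: strand 1 ascends the +z axis (5' to 3'), strand 2
#' is generated by a dyad so the duplex is antiparallel. The template's frame
#' is the identity: z along the helix axis oriented 5'->3' of strand 1, x
#' towards the strand-1 5' sugar bead.
#'
#' @param nbp number of base pairs (>= 1)
#' @param ff [ForceFieldParams-class]
#' @return list with `coords` (6*nbp x 3 matrix; rows are P,S,B of strand-1
#'   residues in ascending order, then P,S,B of strand-2 residues in
#'   ascending *sequence* order) and `pairRows` bookkeeping.
#' @export
buildAformHelix <- function(nbp, ff = forceFieldParams()) {
  if (nbp < 1) stop("a helix needs at least one pair")
  p <- ff@params
  dyadT <- .rotz(p$dyad) %*% diag(c(1, -1, -1))
  beads1 <- function(k) {   # strand 1, pair index k (0-based)
    base <- rbind(.cyl(p$r_P, p$phi_P, p$z_P),
                  .cyl(p$r_S, p$phi_S, p$z_S),
                  .cyl(p$r_B, p$phi_B, p$z_B))
    t(.rotz(k * p$twist) %*% t(base)) +
      matrix(c(0, 0, k * p$rise), nrow(base), 3, byrow = TRUE)
  }
  beads2 <- function(k) {   # strand 2 residue paired with strand-1 pair k
    base <- rbind(.cyl(p$r_P, p$phi_P, p$z_P),
                  .cyl(p$r_S, p$phi_S, p$z_S),
                  .cyl(p$r_B, p$phi_B, p$z_B))
    t(.rotz(k * p$twist) %*% dyadT %*% t(base)) +
      matrix(c(0, 0, k * p$rise), nrow(base), 3, byrow = TRUE)
  }
  s1 <- do.call(rbind, lapply(0:(nbp - 1), beads1))
  ## strand 2 in ascending sequence order corresponds to descending pair index
  s2 <- do.call(rbind, lapply((nbp - 1):0, beads2))
  coords <- rbind(s1, s2)
  rownames(coords) <- NULL
  list(coords = coords, nbp = nbp,
       ## row of the S bead of strand-1 residue k (1-based k)
       s1S = 3 * seq_len(nbp) - 1, s2S = 6 * nbp + 2 - 3 * seq_len(nbp))
}

#' Reference geometry measured on the ideal template
#'
#' Bond lengths, backbone angles and backbone dihedral targets used for
#' flexible regions are not independent constants: they are measured on the
#' ideal A-form template so that helix boundaries relax to strain-free
#' geometry.
#' @param ff [ForceFieldParams-class]
#' @return named list of derived constants
#' @keywords internal
aformReference <- function(ff) {
  tpl <- buildAformHelix(8, ff)$coords
  P <- function(k) tpl[3 * k - 2, ]; S <- function(k) tpl[3 * k - 1, ]
  B <- function(k) tpl[3 * k, ]
  d <- function(a, b) sqrt(sum((a - b)^2))
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  dih <- function(a, b, c, dd) {
    b1 <- b - a; b2 <- c - b; b3 <- dd - c
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  k <- 4  # mid-helix residue of strand 1
  list(
    b_PS = d(P(k), S(k)),           # P(i)-S(i)
    b_SP = d(S(k), P(k + 1)),       # S(i)-P(i+1)
    b_SB = d(S(k), B(k)),           # S(i)-B(i)
    theta_PSP = ang(P(k), S(k), P(k + 1)),
    theta_SPS = ang(S(k), P(k + 1), S(k + 1)),
    ## backbone dihedrals flanking residue k: (S-,P,S,P+) and (P,S,P+,S+)
    phi_SPSP = dih(S(k - 1), P(k), S(k), P(k + 1)),
    phi_PSPS = dih(P(k), S(k), P(k + 1), S(k + 1)),
    pp_intra = d(P(k), P(k + 1)),
    ss_intra = d(S(k), S(k + 1)),
    bb_intra = d(B(k), B(k + 1)),
    ss_cross = d(S(k), tpl[3 * (2 * 8 - k + 1) - 1, ]),
    axis_rise = ff@params$rise)
}
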