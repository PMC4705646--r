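#' Coarse-grained force-field parameters
#'
#' Returns the full parameter set of the energy function with documented
#' defaults; any constant can be overridden by name. The model is
#' deliberately minimal: harmonic bonds and (soft) angles along the backbone,
#' periodic backbone dihedrals only for noncanonically paired residues (at
#' one-fourth the canonical strength, whose role is otherwise played by the
#' rigid helix groups), purely repulsive soft-sphere excluded volume, and a
#' weak Gaussian attraction between the base beads of noncanonically paired
#' residues. Electrostatics and sequence-dependent attractions are absent by
#' design: the ensemble should reflect chain connectivity and sterics only.
#'
#' Geometry defaults describe an idealized A-form duplex built from fiber-type
#' helical parameters (rise 2.81 A, twist 32.7 deg) with beads at
#' phosphate-, sugar(C1')- and glycosidic-nitrogen-like cylindrical
#' positions; the emergent template has ~5.9 A intra-strand P-P spacing and
#' ~10.4 A cross-pair S-S separation (about the span of a canonical base
#' pair, the origin of the 14 A contact cutoff used in the analysis stack).
#' Excluded-volume radii are sized so the ideal duplex template itself has
#' zero repulsion energy while two duplexes cannot thread through each other.
#'
#' @param ... named overrides, e.g. `forceFieldParams(k_ev = 10)`.
#' @return a [ForceFieldParams-class] object.
#' @details Parameters (units):
#' \describe{
#'   \item{rise, twist}{A-form rise (A) and twist (deg) per base-pair step.}
#'   \item{r_P, phi_P, z_P, r_S, phi_S, z_S, r_B, phi_B, z_B}{cylindrical
#'     bead placement (radius A, azimuth deg, axial offset A).}
#'   \item{dyad}{azimuthal phase of the dyad relating the two strands (deg).}
#'   \item{k_bond}{backbone/bead bond constant, kcal/mol/A^2 (E = k/2 dx^2).}
#'   \item{k_angle}{backbone bending constant, kcal/mol/rad^2.}
#'   \item{k_dihedral, k_dihedral_noncanonical}{periodic backbone dihedral
#'     constants (kcal/mol); noncanonical is fixed at one-fourth canonical.}
#'   \item{k_ev, ev_*}{soft-sphere repulsion constant and per-type radii (A).}
#'   \item{attr_eps, attr_r0, attr_w}{paired-base attraction well depth
#'     (kcal/mol, capped at 0.5), centre and width (A).}
#'   \item{nc_noe_k, nc_noe_fmax}{constants of the fixed internal NOEs of
#'     noncanonical pairs (B-B window 5.5-7.5 A, S-S window 11-14 A).}
#'   \item{b2_bond}{bond length of the steric filler bead (A).}
#'   \item{s_anchor}{atom the S bead maps to ("C1'" by default; "C4'" is the
#'     one-line alternative).}
#'   \item{R}{gas constant, kcal/(mol K).}
#' }
#' @export
forceFieldParams <- function(...) {
  p <- list(
    rise = 2.81, twist = 32.7,
    r_P = 8.9, phi_P = -30, z_P = 2.5,
    r_S = 9.4, phi_S = 0,   z_S = 0,
    r_B = 8.0, phi_B = 3,   z_B = 0.5,
    dyad = 67.2,
    k_bond = 20, k_angle = 5,
    k_dihedral = 8, k_dihedral_noncanonical = 2,
    k_ev = 20,
    ev_P = 2.0, ev_S = 2.4, ev_B = 2.2, ev_B2 = 2.2,
    attr_eps = 0.3, attr_r0 = 6.5, attr_w = 1.5,
    nc_noe_k = 2, nc_noe_fmax = 2,
    b2_bond = 3.5,
    s_anchor = "C1'",
    R = .RGAS)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown force-field parameter: ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (!("k_dihedral_noncanonical" %in% names(over)) &&
      "k_dihedral" %in% names(over))
    p$k_dihedral_noncanonical <- p$k_dihedral / 4
  new("ForceFieldParams", params = p)
}

#' Look up a force-field constant
#' @param ff [ForceFieldParams-class]; @param name parameter name
#' @export
ffParam <- function(ff, name) {
  if (!name %in% names(ff@params)) stop("no such parameter: ", name)
  ff@params[[name]]
}

.evRadius <- function(ff, type) {
  unlist(ff@params[paste0("ev_", type)], use.names = FALSE)
}
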