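## Central S4 classes. Validity methods enforce the structural invariants the
## rest of the package relies on; accessors live next to the module that owns
## the class.

#' SecondaryStructure: sequence plus validated pair table
#'
#' Holds an RNA sequence, its base-pair table (1-based positions, `i < j`,
#' each position in at most one pair) and the pair classes. Canonical pairs
#' become rigid A-form helices during chain building; noncanonical internal
#' loop pairs stay flexible and are enforced through weak attractions and
#' flat-bottom distance restraints instead. An optional numbering map carries
#' author/crystal residue numbers (e.g. "A39") so restraint rosters printed in
#' crystal numbering can be used verbatim.
#'
#' @slot sequence character vector of residue letters (A/C/G/U/N), one per
#'   position.
#' @slot pairs data.frame with columns `i`, `j`, `class`
#'   (`canonical`/`noncanonical`).
#' @slot numbering integer vector, same length as the sequence: the external
#'   residue number of each 1-based position (defaults to 1..n).
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
  representation(sequence = "character", pairs = "data.frame",
                 numbering = "integer"))

setValidity("SecondaryStructure", function(object) {
  n <- length(object@sequence)
  p <- object@pairs
  msgs <- character()
  if (!all(c("i", "j", "class") %in% names(p)))
    return("pairs must have columns i, j, class")
  if (nrow(p)) {
    if (any(p$i >= p$j)) msgs <- c(msgs, "pairs must satisfy i < j")
    if (any(p$i < 1 | p$j > n)) msgs <- c(msgs, "pair positions out of range")
    if (anyDuplicated(c(p$i, p$j)))
      msgs <- c(msgs, "a position appears in more than one pair")
    if (!all(p$class %in% c("canonical", "noncanonical")))
      msgs <- c(msgs, "pair class must be canonical or noncanonical")
  }
  if (!all(object@sequence %in% c("A", "C", "G", "U", "N")))
    msgs <- c(msgs, "sequence letters must be A/C/G/U/N")
  if (length(object@numbering) != n)
    msgs <- c(msgs, "numbering must have one entry per position")
  if (anyDuplicated(object@numbering))
    msgs <- c(msgs, "numbering map must be injective")
  if (length(msgs)) msgs else TRUE
})

#' TopologyGraph: helices, linkers and junction classification
#'
#' Decomposition of a [SecondaryStructure] into maximal canonical helices
#' (rigid units) and maximal unpaired runs (flexible units), together with a
#' unit adjacency graph used for linker classification and flexible-pivot
#' counting. Named regions (P1..P9, L2, J8, ...) are attached from a regions
#' table; they are data, never hard-coded.
#'
#' @slot ss the parent [SecondaryStructure].
#' @slot helices data.frame: `name`, `s1_start`, `s1_end`, `s2_start`,
#'   `s2_end`, `n_bp` (strand1 ascends, strand2 the reverse complement run).
#' @slot units data.frame of chain units (`id`, `kind` helix/linker, `first`,
#'   `last`, `helix` index or NA, `n_res`).
#' @slot unitOf integer vector mapping each residue to its unit id.
#' @slot edges data.frame of unit adjacency (`from`, `to`, `nt` = number of
#'   single-stranded residues of the linker unit, 0 for direct helix-helix
#'   bonds).
#' @slot regions named list of integer vectors (1-based residue sets).
#' @exportClass TopologyGraph
setClass("TopologyGraph",
  representation(ss = "SecondaryStructure", helices = "data.frame",
                 units = "data.frame", unitOf = "integer",
                 edges = "data.frame", regions = "list"))

setValidity("TopologyGraph", function(object) {
  n <- length(object@ss@sequence)
  if (length(object@unitOf) != n)
    return("unitOf must cover every residue exactly once")
  if (any(is.na(object@unitOf)))
    return("every residue must belong to exactly one unit")
  h <- object@helices
  if (nrow(h)) {
    occ <- c(unlist(Map(seq, h$s1_start, h$s1_end)),
             unlist(Map(seq, h$s2_start, h$s2_end)))
    if (anyDuplicated(occ)) return("helix strand ranges overlap")
  }
  bad <- vapply(object@regions, function(r) any(r < 1 | r > n), logical(1))
  if (any(bad)) return("region sets reference invalid positions")
  TRUE
})

#' ForceFieldParams: coarse-grained energy-function constants
#'
#' All constants of the energy function, overridable individually. The model
#' has no electrostatics and no sequence-dependent attraction; the only
#' attractive term is a weak short-range well between base beads of
#' noncanonically paired residues. Units: lengths in Angstrom, energies in
#' kcal/mol, force constants in kcal/mol/A^2 (bonds, flat-bottom restraints)
#' or kcal/mol/rad^2 (angles) or kcal/mol (periodic dihedrals).
#'
#' @slot params named list of constants; see [forceFieldParams()].
#' @exportClass ForceFieldParams
setClass("ForceFieldParams", representation(params = "list"))

setValidity("ForceFieldParams", function(object) {
  p <- object@params
  num <- vapply(p[!(names(p) %in% c("s_anchor"))], is.numeric, logical(1))
  if (!all(num)) return("all force-field parameters must be numeric")
  ks <- c("k_bond", "k_angle", "k_dihedral", "k_ev", "attr_eps")
  if (any(unlist(p[ks]) < 0)) return("force constants must be >= 0")
  if (!isTRUE(all.equal(p$k_dihedral_noncanonical, p$k_dihedral / 4)))
    return("noncanonical dihedral constant must be one-fourth the canonical")
  if (p$attr_eps > 0.5 + 1e-12)
    return("paired-base attraction well depth capped at 0.5 kcal/mol")
  TRUE
})

#' CoarseChain: the built three-bead model
#'
#' The P/S/B bead model of one structure: bead table and initial coordinates,
#' rigid A-form groups (one per canonical helix), the assembled energy terms,
#' intrinsic restraints of noncanonical pairs, and precomputed Monte Carlo
#' move tables. Bead count is `3 * n_residues + n_noncanonical_pairs` (each
#' noncanonical pair adds one steric filler bead on one of its bases).
#'
#' @slot ss [SecondaryStructure]; @slot topology [TopologyGraph]
#' @slot ff [ForceFieldParams]
#' @slot beads data.frame (`residue`, `type` in P/S/B/B2)
#' @slot coords numeric matrix n_beads x 3 (initial conformation)
#' @slot group integer per bead: rigid group id, 0 = flexible
#' @slot groups named list: helix name -> bead indices
#' @slot templates named list: helix name -> template coordinates (same row
#'   order as `groups`), the exact rigid geometry
#' @slot terms list of assembled energy-term tables handed to the sampler
#' @slot moves list of precomputed move tables (pivots, segments, helices,
#'   local beads)
#' @slot buildInfo list: seed, relaxation diagnostics, gap report
#' @exportClass CoarseChain
setClass("CoarseChain",
  representation(ss = "SecondaryStructure", topology = "TopologyGraph",
                 ff = "ForceFieldParams", beads = "data.frame",
                 coords = "matrix", group = "integer", groups = "list",
                 templates = "list", terms = "list", moves = "list",
                 buildInfo = "list"))

setValidity("CoarseChain", function(object) {
  n <- length(object@ss@sequence)
  nnc <- sum(object@ss@pairs$class == "noncanonical")
  if (nrow(object@beads) != 3L * n + nnc)
    return("bead count must be 3*n_residues + n_noncanonical_pairs")
  if (nrow(object@coords) != nrow(object@beads))
    return("coords must have one row per bead")
  if (length(object@group) != nrow(object@beads))
    return("group must have one entry per bead")
  TRUE
})

#' RestraintSet: NOE, dihedral and radius-of-gyration restraints
#'
#' Flat-bottom ("NOE") distance restraints are zero inside `[r_min, r_max]`,
#' harmonic with `k_min`/`k_max` outside, and continue linearly once the
#' restraint force reaches `f_max`. Dihedral restraints are periodic,
#' `K (1 - cos(phi - phi0))`. The optional collective restraint is harmonic
#' in the all-bead radius of gyration.
#'
#' @slot kind character tag ("TH", "L9J5", "RG32", "custom", "none")
#' @slot noe data.frame (`i`, `j` bead indices, `rmin`, `rmax`, `kmin`,
#'   `kmax`, `fmax`)
#' @slot dihedral data.frame (`i`,`j`,`k`,`l` beads, `phi0` deg, `K`)
#' @slot rg list with `target` and `k`, or empty list
#' @exportClass RestraintSet
setClass("RestraintSet",
  representation(kind = "character", noe = "data.frame",
                 dihedral = "data.frame", rg = "list"))

setValidity("RestraintSet", function(object) {
  if (nrow(object@noe)) {
    if (any(object@noe$rmin > object@noe$rmax))
      return("NOE restraints need r_min <= r_max")
    if (any(unlist(object@noe[c("kmin", "kmax", "fmax")]) < 0))
      return("restraint constants must be >= 0")
  }
  if (nrow(object@dihedral) && any(object@dihedral$K < 0))
    return("dihedral restraint K must be >= 0")
  if (length(object@rg) && (object@rg$k < 0 || object@rg$target <= 0))
    return("rg restraint needs positive target and k >= 0")
  TRUE
})

#' SamplerConfig: Monte Carlo / replica-exchange settings
#'
#' @slot temps strictly increasing temperature ladder in K (default: eight
#'   exponentially spaced values spanning 300-400 K)
#' @slot exchangeEvery moves between neighbour exchange attempts
#' @slot totalMoves total MC moves per replica
#' @slot recordEvery record a frame from the replica at the analysis
#'   temperature every this many of its moves
#' @slot seed integer RNG seed (recorded in every output)
#' @slot equilFrac fraction of recorded frames marked as equilibration
#' @slot moveWeights named numeric: pivot/segment/helix/local proposal weights
#' @slot amplitudes named numeric: max pivot/segment/helix rotation (deg),
#'   helix translation and local displacement (A)
#' @slot options list: `ev` (sterics on), `angles` (bending terms on),
#'   `record` bead selection ("S", "PS" or "all")
#' @exportClass SamplerConfig
setClass("SamplerConfig",
  representation(temps = "numeric", exchangeEvery = "integer",
                 totalMoves = "integer", recordEvery = "integer",
                 seed = "integer", equilFrac = "numeric",
                 moveWeights = "numeric", amplitudes = "numeric",
                 options = "list"))

setValidity("SamplerConfig", function(object) {
  if (length(object@temps) < 1 || any(diff(object@temps) <= 0))
    return("temperature ladder must be strictly increasing")
  if (object@equilFrac < 0 || object@equilFrac >= 1)
    return("equilFrac must be in [0, 1)")
  if (object@totalMoves < object@exchangeEvery)
    return("totalMoves must be at least exchangeEvery")
  TRUE
})

#' TrajectoryEnsemble: recorded conformations with provenance
#'
#' Frames recorded at the analysis temperature (the lowest rung of the
#' ladder) with replica/step provenance, the per-frame all-bead radius of
#' gyration, exchange statistics, the config snapshot and the equilibration
#' marker. Frames store the configured bead selection (sugar beads by
#' default); `sRow`/`pRow` map residues to frame rows.
#'
#' @slot frames numeric array `n_frames x n_sel x 3`
#' @slot selection integer bead indices recorded
#' @slot sRow,pRow integer per residue: row of its S (P) bead in the frame,
#'   or NA when not recorded
#' @slot rg numeric per frame (all beads)
#' @slot step,replica integer per frame
#' @slot helices list of per-helix metadata (residues, template S coords)
#'   used for Euler-frame fitting
#' @slot config [SamplerConfig]; @slot exchange data.frame of per-pair
#'   attempt/accept counts; @slot equilFrames frames to discard
#' @slot meta list (ground truth for synthetic ensembles, timings, energies)
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  representation(frames = "array", selection = "integer", sRow = "integer",
                 pRow = "integer", rg = "numeric", step = "integer",
                 replica = "integer", helices = "list",
                 config = "SamplerConfig", exchange = "data.frame",
                 equilFrames = "integer", meta = "list"))

setValidity("TrajectoryEnsemble", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3 || d[3] != 3)
    return("frames must be an n_frames x n_beads x 3 array")
  if (length(object@rg) && length(object@rg) != d[1])
    return("rg must have one value per frame")
  TRUE
})

#' EulerSeries: per-frame interhelical Euler angles
#'
#' Angles of the ZYZ decomposition of the rotation taking the first helix
#' frame into the second, in degrees: `alpha`, `gamma` in [-180, 180),
#' `beta` in [0, 180].
#'
#' @slot angles numeric matrix n x 3 (alpha, beta, gamma)
#' @slot pair character(2): helix names
#' @slot frames integer: indices of the trajectory frames used
#' @slot meta list (bin conventions, provenance)
#' @exportClass EulerSeries
setClass("EulerSeries",
  representation(angles = "matrix", pair = "character", frames = "integer",
                 meta = "list"))

setValidity("EulerSeries", function(object) {
  a <- object@angles
  if (ncol(a) != 3) return("angles must have three columns")
  if (nrow(a)) {
    if (any(a[, 1] < -180 | a[, 1] >= 180 + 1e-9) ||
        any(a[, 3] < -180 | a[, 3] >= 180 + 1e-9))
      return("alpha/gamma must lie in [-180, 180)")
    if (any(a[, 2] < -1e-9 | a[, 2] > 180 + 1e-9))
      return("beta must lie in [0, 180]")
  }
  TRUE
})

#' OrientationHistogram: binned (alpha, beta, gamma) counts
#'
#' 45-degree binning gives 8 x 4 x 8 = 256 cells per variable; a joint
#' histogram of two variables has 256^2 cells. Counts are stored sparsely as
#' a named count table over occupied cells.
#'
#' @slot counts named numeric vector of cell counts (names = cell ids)
#' @slot nCells total number of cells in the (possibly joint) space
#' @slot n total count
#' @slot binWidth degrees
#' @slot joint logical
#' @exportClass OrientationHistogram
setClass("OrientationHistogram",
  representation(counts = "numeric", nCells = "numeric", n = "numeric",
                 binWidth = "numeric", joint = "logical"))

setValidity("OrientationHistogram", function(object) {
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (abs(sum(object@counts) - object@n) > 1e-6)
    return("total count must equal the sum of cell counts")
  TRUE
})

#' FreeEnergyResult: contact probability and dG_topo with uncertainty
#'
#' @slot p contact probability; @slot nFrames,nContact frame counts
#' @slot dG kcal/mol at the analysis temperature (Inf/-Inf magnitude bound
#'   when p hits 0 or 1; see `bound`)
#' @slot ci numeric(2): block-bootstrap interval for dG
#' @slot bound logical: TRUE when dG is a one-sided pseudocount bound
#' @slot temperature K; @slot tag conditioning tag
#' @exportClass FreeEnergyResult
setClass("FreeEnergyResult",
  representation(p = "numeric", nFrames = "integer", nContact = "integer",
                 dG = "numeric", ci = "numeric", bound = "logical",
                 temperature = "numeric", tag = "character"))

setValidity("FreeEnergyResult", function(object) {
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  if (!object@bound && !is.finite(object@dG) && object@p > 0 && object@p < 1)
    return("dG must be finite for 0 < p < 1")
  TRUE
})

#' RunManifest: provenance record for a pipeline invocation
#'
#' @slot fields named list: config snapshot, seeds, input digests, package
#'   version, per-stage timings, output inventory
#' @exportClass RunManifest
setClass("RunManifest", representation(fields = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "SecondaryStructure", function(object) {
  p <- object@pairs
  cat(sprintf("SecondaryStructure: %d nt, %d pairs (%d canonical, %d noncanonical)\n",
              length(object@sequence), nrow(p),
              sum(p$class == "canonical"), sum(p$class == "noncanonical")))
  if (!identical(object@numbering, seq_along(object@sequence)))
    cat(sprintf("  external numbering %d..%d\n",
                object@numbering[1], tail(object@numbering, 1)))
})

setMethod("show", "TopologyGraph", function(object) {
  cat(sprintf("TopologyGraph: %d helices, %d linker units, %d named regions\n",
              nrow(object@helices),
              sum(object@units$kind == "linker"), length(object@regions)))
  if (nrow(object@helices))
    cat("  helices:", paste(object@helices$name, collapse = " "), "\n")
})

setMethod("show", "ForceFieldParams", function(object) {
  cat("ForceFieldParams:\n")
  p <- object@params
  for (k in names(p))
    cat(sprintf("  %-26s %s\n", k, paste(signif(unlist(p[[k]]), 5), collapse = " ")))
})

setMethod("show", "CoarseChain", function(object) {
  cat(sprintf("CoarseChain: %d residues, %d beads, %d rigid groups\n",
              length(object@ss@sequence), nrow(object@beads),
              length(object@groups)))
  cat(sprintf("  move table: %d pivots, %d segments, %d helix bodies, %d local beads\n",
              length(object@moves$pivotSets), nrow(object@moves$segments),
              length(object@groups), length(object@moves$localBeads)))
})

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet [%s]: %d NOE, %d dihedral%s\n", object@kind,
              nrow(object@noe), nrow(object@dihedral),
              if (length(object@rg)) sprintf(", Rg target %g A", object@rg$target) else ""))
})

setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf("SamplerConfig: %d temps %.0f-%.0f K, %d moves/replica, exchange every %d, seed %d\n",
              length(object@temps), min(object@temps), max(object@temps),
              object@totalMoves, object@exchangeEvery, object@seed))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  d <- dim(object@frames)
  cat(sprintf("TrajectoryEnsemble: %d frames x %d beads (%s), %d marked equilibration\n",
              d[1], d[2],
              if (length(object@meta$record)) object@meta$record else "sel",
              object@equilFrames))
  if (length(object@rg))
    cat(sprintf("  mean all-bead Rg (post-equil): %.1f A\n",
                mean(object@rg[postEquilIdx(object)])))
})

setMethod("show", "EulerSeries", function(object) {
  cat(sprintf("EulerSeries %s-%s: %d frames\n", object@pair[1], object@pair[2],
              nrow(object@angles)))
})

setMethod("show", "FreeEnergyResult", function(object) {
  cat(sprintf("FreeEnergyResult [%s]: p = %.4g (%d/%d frames), dG_topo = %s kcal/mol [%.2f, %.2f]%s\n",
              object@tag, object@p, object@nContact, object@nFrames,
              formatC(object@dG, digits = 3, format = "fg"),
              object@ci[1], object@ci[2],
              if (object@bound) " (bound)" else ""))
})

setMethod("show", "RunManifest", function(object) {
  cat("RunManifest:\n")
  str(object@fields, max.level = 1, give.attr = FALSE)
})
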