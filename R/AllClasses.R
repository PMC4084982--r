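#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core structural containers
## ---------------------------------------------------------------------------

#' AtomicModel: a named bead/atom model with coordinates, masses and groups
#'
#' The substrate every other component consumes. Coordinates are in Angstrom,
#' masses in amu. `groups` maps a group name to the integer indices of its
#' member atoms; groups drive umbrella restraints, steering targets and all
#' geometric selections.
#'
#' @slot atoms data.frame with columns `name` (atom name), `element`,
#'   `resno` (residue number), `resname`, `chain`.
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot masses numeric vector of per-atom masses in amu (all > 0).
#' @slot groups named list of integer index vectors into the atom table.
#'
#' @exportClass AtomicModel
setClass("AtomicModel",
  representation(
    atoms = "data.frame",
    coords = "matrix",
    masses = "numeric",
    groups = "list"
  )
)

setValidity("AtomicModel", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have 3 columns")
  if (nrow(object@atoms) != n)
    msg <- c(msg, "atom table and coords disagree in length")
  if (length(object@masses) != n)
    msg <- c(msg, "masses and coords disagree in length")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (any(!is.finite(object@masses)) || any(object@masses <= 0))
    msg <- c(msg, "all masses must be finite and > 0")
  if (length(object@groups)) {
    idx <- unlist(object@groups, use.names = FALSE)
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      msg <- c(msg, "group tags reference atom indices outside the model")
  }
  if (length(msg)) msg else TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' @slot rotation 3x3 proper orthogonal matrix (det = +1).
#' @slot translation length-3 numeric, Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-7)
      msg <- c(msg, "rotation must be orthogonal")
    if (abs(det(R) - 1) > 1e-9)
      msg <- c(msg, "rotation must be proper (det = +1 within 1e-9)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' SelectionSpec: composable atom-selection predicate
#'
#' Predicates on chain id, residue-number set and atom names combine by
#' intersection within one spec; `selUnion()` / `selIntersect()` compose
#' specs. Resolution against an AtomicModel is deterministic and
#' order-independent (indices are returned sorted and unique).
#'
#' @slot chain character vector of chain ids (empty = any).
#' @slot resno integer vector of residue numbers (empty = any).
#' @slot name character vector of atom names (empty = any).
#' @slot group character vector of group-tag names (empty = unused).
#' @slot op "leaf", "union" or "intersect".
#' @slot parts list of child SelectionSpec objects for union/intersect.
#' @exportClass SelectionSpec
setClass("SelectionSpec",
  representation(
    chain = "character", resno = "integer", name = "character",
    group = "character", op = "character", parts = "list"
  ),
  prototype(chain = character(), resno = integer(), name = character(),
            group = character(), op = "leaf", parts = list())
)

## ---------------------------------------------------------------------------
## Density maps
## ---------------------------------------------------------------------------

#' DensityMap: a regular 3-D density grid
#'
#' @slot origin position of the first voxel center, Angstrom.
#' @slot spacing voxel spacing per axis, Angstrom.
#' @slot dims integer grid dimensions (nx, ny, nz).
#' @slot values 3-D numeric array of voxel values, dim == dims.
#' @slot resolution nominal map resolution in Angstrom (half-width of the
#'   Fourier-space Gaussian; see [synthesizeMap()]).
#' @exportClass DensityMap
setClass("DensityMap",
  representation(
    origin = "numeric", spacing = "numeric", dims = "integer",
    values = "array", resolution = "numeric"
  )
)

setValidity("DensityMap", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be 3 positive integers")
  if (!identical(dim(object@values), as.integer(object@dims)))
    msg <- c(msg, "values array dims must equal dims slot")
  if (length(object@origin) != 3L || length(object@spacing) != 3L)
    msg <- c(msg, "origin and spacing must have length 3")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' EMFitParams: parameters of the density-fitting term
#'
#' @slot resolution map resolution in Angstrom.
#' @slot nNeighbor kernel truncation: number of nearest grid planes per axis
#'   in each direction (3 or 4).
#' @slot wEM dimensionless fitting weight (relative to the mean structural
#'   force magnitude).
#' @slot kEM derived energy weight (set by [scaleWeight()]).
#' @exportClass EMFitParams
setClass("EMFitParams",
  representation(resolution = "numeric", nNeighbor = "integer",
                 wEM = "numeric", kEM = "numeric"),
  prototype(nNeighbor = 4L, wEM = 0, kEM = 0)
)

setValidity("EMFitParams", function(object) {
  msg <- character()
  if (!object@nNeighbor %in% c(3L, 4L))
    msg <- c(msg, "nNeighbor must be 3 or 4")
  if (object@wEM < 0) msg <- c(msg, "wEM must be >= 0")
  if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
  if (length(msg)) msg else TRUE
})

#' VoxelPointSet: thresholded voxels treated as a weighted point cloud
#'
#' @slot points matrix of voxel-center coordinates (Angstrom).
#' @slot values voxel values (used as weights).
#' @slot threshold the density threshold applied.
#' @slot voxelVolume volume of one voxel, Angstrom^3.
#' @exportClass VoxelPointSet
setClass("VoxelPointSet",
  representation(points = "matrix", values = "numeric",
                 threshold = "numeric", voxelVolume = "numeric")
)

## ---------------------------------------------------------------------------
## Sampling engine
## ---------------------------------------------------------------------------

#' ToyPotential: coarse structural potential standing in for a force field
#'
#' Harmonic bonds use V = k (r - r0)^2; soft-core repulsion uses
#' V = eps (sigma/r)^12. `fields` is a list of external per-atom analytic
#' terms, each a list(atoms = integer indices, fun = function(coords)
#' list(energy =, forces =)) operating on the selected rows.
#'
#' @slot bonds data.frame with columns i, j, k (kcal/mol/A^2), r0 (A).
#' @slot repulsion data.frame with columns i, j, eps (kcal/mol), sigma (A).
#' @slot fields list of external field terms.
#' @exportClass ToyPotential
setClass("ToyPotential",
  representation(bonds = "data.frame", repulsion = "data.frame",
                 fields = "list"),
  prototype(
    bonds = data.frame(i = integer(), j = integer(),
                       k = numeric(), r0 = numeric()),
    repulsion = data.frame(i = integer(), j = integer(),
                           eps = numeric(), sigma = numeric()),
    fields = list())
)

#' WindowRecord: one cycle of the EM-fitting / umbrella-sampling protocol
#'
#' @slot index window number (1-based).
#' @slot wEM fitting weight used in the window's EM-fitting phase.
#' @slot biasCenters matrix (nGroups x 3) of umbrella centers, Angstrom.
#' @slot biasK per-group force constants, kcal/mol/A^2.
#' @slot biasForm "k" (V = k |dR|^2) or "k/2" (V = k/2 |dR|^2).
#' @slot series 3-D array (nSamples x nGroups x 3) of sampled group COMs.
#' @slot snapshot coordinates at the restart point of the sampling phase.
#' @slot finalCoords coordinates at the end of the window.
#' @slot cc correlation coefficient at the end of the fitting phase (NA when
#'   no density term was active).
#' @slot comShift max per-group COM displacement realized in the fitting
#'   phase, Angstrom.
#' @exportClass WindowRecord
setClass("WindowRecord",
  representation(index = "integer", wEM = "numeric",
                 biasCenters = "matrix", biasK = "numeric",
                 biasForm = "character", series = "array",
                 snapshot = "matrix", finalCoords = "matrix",
                 cc = "numeric", comShift = "numeric")
)

## ---------------------------------------------------------------------------
## WHAM
## ---------------------------------------------------------------------------

#' UmbrellaDataset: biased samples of the umbrella-coordinate vector R
#'
#' Each window holds samples of the nGroups x 3 vector of group centers of
#' mass, plus the bias spec that generated them, so every window's bias
#' energy is recomputable from its spec and any sample.
#'
#' @slot windows list; each element list(samples = array n x g x 3,
#'   centers = matrix g x 3, k = numeric g, form = "k" or "k/2").
#' @slot temperature Kelvin.
#' @exportClass UmbrellaDataset
setClass("UmbrellaDataset",
  representation(windows = "list", temperature = "numeric")
)

setValidity("UmbrellaDataset", function(object) {
  msg <- character()
  for (w in object@windows) {
    if (!all(c("samples", "centers", "k", "form") %in% names(w))) {
      msg <- c(msg, "each window needs samples, centers, k, form")
      break
    }
    if (dim(w$samples)[1] < 1L) msg <- c(msg, "windows must have n_j > 0")
    if (!w$form %in% c("k", "k/2")) msg <- c(msg, "unknown bias form tag")
  }
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (length(msg)) msg else TRUE
})

#' WhamSolution: self-consistent window free energies and sample weights
#'
#' @slot F per-window free-energy shifts, kcal/mol (first window anchored 0).
#' @slot logWeights log unbiased weight per pooled sample (normalized so the
#'   weights sum to 1).
#' @slot windowIndex window of origin per pooled sample.
#' @slot temperature Kelvin.
#' @slot convergence list(iterations, maxDeltaF, tolerance).
#' @exportClass WhamSolution
setClass("WhamSolution",
  representation(F = "numeric", logWeights = "numeric",
                 windowIndex = "integer", temperature = "numeric",
                 convergence = "list")
)

setValidity("WhamSolution", function(object) {
  s <- sum(exp(object@logWeights))
  if (abs(s - 1) > 1e-6) "weights must sum to 1" else TRUE
})

#' ProjectionFrame: references defining the R1 / R2 reaction coordinates
#'
#' @slot mask logical vector over umbrella groups: TRUE for groups entering
#'   the ratchet projection (typically all subunit groups, excluding
#'   factor-side groups whose motion is not ratchet-like).
#' @slot Ri matrix (nGroups x 3) initial umbrella-coordinate reference.
#' @slot Rf matrix (nGroups x 3) final (target) reference.
#' @slot eTRNA unit 3-vector of tRNA travel (initial E-site minus initial
#'   P-site anchor).
#' @slot rEI initial E-site anchor position (Angstrom).
#' @slot rPI initial P-site anchor position (Angstrom).
#' @slot superpose logical: rigidly superpose each sample's masked
#'   coordinates onto Ri before projecting R1.
#' @exportClass ProjectionFrame
setClass("ProjectionFrame",
  representation(mask = "logical", Ri = "matrix", Rf = "matrix",
                 eTRNA = "numeric", rEI = "numeric", rPI = "numeric",
                 superpose = "logical"),
  prototype(superpose = TRUE)
)

setValidity("ProjectionFrame", function(object) {
  msg <- character()
  if (length(object@mask) != nrow(object@Ri) ||
      nrow(object@Ri) != nrow(object@Rf))
    msg <- c(msg, "mask, Ri, Rf must agree in group count")
  if (abs(sqrt(sum(object@eTRNA^2)) - 1) > 1e-8)
    msg <- c(msg, "eTRNA must be a unit vector")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Path search and geometry
## ---------------------------------------------------------------------------

#' SteeringState: adaptive steered-targeting controller state
#'
#' One row per steered group: previous-window mean position, the current
#' way-point target, step length delta (Angstrom, within [0.3, 0.6]),
#' progress threshold Delta = delta/2, and force constant k in pN/A.
#'
#' @slot meanPrev matrix (nSteered x 3), previous-window mean positions.
#' @slot targets list of way-point matrices (nSteered x 3), visited in order.
#' @slot stage current way-point stage (1-based).
#' @slot delta per-group step length, Angstrom.
#' @slot k per-group force constant, pN/A.
#' @slot switchRadius way-point switch radius, Angstrom.
#' @exportClass SteeringState
setClass("SteeringState",
  representation(meanPrev = "matrix", targets = "list", stage = "integer",
                 delta = "numeric", k = "numeric", switchRadius = "numeric"),
  prototype(stage = 1L, switchRadius = 2)
)

setValidity("SteeringState", function(object) {
  msg <- character()
  if (any(object@delta < 0.3 - 1e-12) || any(object@delta > 0.6 + 1e-12))
    msg <- c(msg, "delta must lie within [0.3, 0.6] Angstrom")
  if (any(object@k < 0)) msg <- c(msg, "force constants must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ScrewMotion: Chasles screw-axis description of a rigid displacement
#'
#' @slot point a point on the screw axis (the one closest to the moving
#'   group's center of mass), Angstrom.
#' @slot direction unit axis direction.
#' @slot angle rotation angle about the axis, degrees.
#' @slot translation translation along the axis, Angstrom.
#' @exportClass ScrewMotion
setClass("ScrewMotion",
  representation(point = "numeric", direction = "numeric",
                 angle = "numeric", translation = "numeric")
)

setValidity("ScrewMotion", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    "direction must be a unit vector" else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic fixtures
## ---------------------------------------------------------------------------

#' ToyRibosomeSpec: parameters of the synthetic two-body ratchet assembly
#'
#' @slot nLarge,nSmall,nHead,nTRNA bead counts of the large body, small body,
#'   head sub-group and each of the two mobile tRNA-like groups.
#' @slot ratchetAmplitude small-body rotation between endpoints, degrees.
#' @slot headAmplitude head swivel between endpoints, degrees.
#' @slot tRNATravel tRNA-group travel between endpoints, Angstrom.
#' @slot gateOpening gate-width change between endpoints, Angstrom.
#' @slot nGroups number of umbrella groups the beads are partitioned into.
#' @slot kIntra,kInter intra-group / inter-group spring constants,
#'   kcal/mol/A^2.
#' @slot barrier collective POST/PRE bistability barrier of the structural
#'   potential, kcal/mol (0 = single POST basin).
#' @slot kConfine condensed-phase confinement constant, kcal/mol/A^2:
#'   anchors immobile beads at their POST positions and confines mobile
#'   beads to a harmonic tube around their POST-to-PRE path.
#' @slot seed RNG seed making the model reproducible.
#' @exportClass ToyRibosomeSpec
setClass("ToyRibosomeSpec",
  representation(nLarge = "integer", nSmall = "integer", nHead = "integer",
                 nTRNA = "integer", ratchetAmplitude = "numeric",
                 headAmplitude = "numeric", tRNATravel = "numeric",
                 gateOpening = "numeric", nGroups = "integer",
                 kIntra = "numeric", kInter = "numeric", barrier = "numeric",
                 kConfine = "numeric", seed = "integer"),
  prototype(nLarge = 80L, nSmall = 50L, nHead = 24L, nTRNA = 6L,
            ratchetAmplitude = 6, headAmplitude = 8, tRNATravel = 4,
            gateOpening = 6, nGroups = 10L, kIntra = 2, kInter = 0.02,
            barrier = 6, kConfine = 0.3, seed = 1L)
)

#' ReferenceLandscape: analytic potential with closed-form free energy
#'
#' @slot kind "harmonic", "doublewell" or "separable2d".
#' @slot params named numeric parameters (see [makeReferenceLandscape()]).
#' @slot temperature Kelvin.
#' @exportClass ReferenceLandscape
setClass("ReferenceLandscape",
  representation(kind = "character", params = "numeric",
                 temperature = "numeric")
)
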