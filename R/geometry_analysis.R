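#' @include AllClasses.R AllGenerics.R structure_model.R
NULL

#' Intersubunit ratchet angle between two structures
#'
#' The model is best-fit onto the reference over the large-subunit
#' selection; the residual rotation best-fitting the model's small subunit
#' onto the reference's is then expressed as a rotation vector and
#' projected onto the ratchet direction e_ratchet (the unit vector from the
#' small-subunit COM to the large-subunit COM of the reference). The
#' reported angle is theta * (e_rot . e_ratchet): rotation about an axis
#' perpendicular to the intersubunit axis contributes nothing, and the sign
#' follows the projection.
#'
#' @param model,reference [AtomicModel-class] objects with matching
#'   selections.
#' @param largeSel,smallSel selections for the large and small subunits.
#' @return signed ratchet angle, degrees.
#' @export
ratchetAngle <- function(model, reference, largeSel = "large",
                         smallSel = "small") {
  fit <- superpose(model, reference, largeSel)
  fitted <- transformModel(model, fit)
  ## rotation carrying the reference small subunit onto the fitted model's:
  ## a model whose small subunit is rotated +theta about e_ratchet relative
  ## to the reference reports +theta
  rot <- superpose(reference, fitted, smallSel, selRef = smallSel)
  aa <- rotationAngleAxis(rot@rotation)
  eR <- centerOfMass(reference, largeSel) - centerOfMass(reference, smallSel)
  eR <- eR / sqrt(sum(eR^2))
  aa$angle * sum(aa$axis * eR)
}

#' Head-rotation angle relative to a reference structure
#'
#' The head axis is the principal axis of the head selection most parallel
#' to the tRNA-travel direction eTRNA, sign-oriented along it. Both
#' structures' head axes are projected onto the plane spanned by eTRNA and
#' eRatchet and the in-plane angle of the model's axis is reported relative
#' to the reference's. The sign convention is clockwise-positive when
#' viewed along the plane normal eTRNA x eRatchet-perp (a right-handed
#' in-plane rotation from eTRNA toward the second basis vector counts
#' negative).
#'
#' @param model,reference [AtomicModel-class] objects.
#' @param headSel head-region selection.
#' @param eTRNA tRNA-travel unit vector (defining the in-plane reference
#'   direction).
#' @param eRatchet ratchet direction (spanning the projection plane with
#'   eTRNA).
#' @param fitSel optional selection to superpose `model` onto `reference`
#'   first (e.g. the large subunit); NULL = structures already aligned.
#' @return signed head angle in degrees, relative to the reference.
#' @export
headAngle <- function(model, reference, headSel = "head", eTRNA, eRatchet,
                      fitSel = NULL) {
  if (!is.null(fitSel))
    model <- transformModel(model, superpose(model, reference, fitSel))
  b1 <- eTRNA / sqrt(sum(eTRNA^2))
  b2 <- eRatchet - sum(eRatchet * b1) * b1
  nb2 <- sqrt(sum(b2 * b2))
  if (nb2 < 1e-9) stop("headAngle: eTRNA and eRatchet are parallel")
  b2 <- b2 / nb2
  axisOf <- function(m) {
    pa <- principalAxes(m, headSel,
                        referenceDirections = matrix(b1, 3, 3))
    dots <- abs(as.numeric(b1 %*% pa$axes))
    ax <- pa$axes[, which.max(dots)]
    if (sum(ax * b1) < 0) ax <- -ax
    ax
  }
  phi <- function(ax) atan2(sum(ax * b2), sum(ax * b1))
  aM <- withCallingHandlers(axisOf(model),
    warning = function(w) invokeRestart("muffleWarning"))
  aR <- withCallingHandlers(axisOf(reference),
    warning = function(w) invokeRestart("muffleWarning"))
  d <- (phi(aM) - phi(aR)) * 180 / pi
  d <- ((d + 180) %% 360) - 180
  -d   # clockwise-positive convention
}

#' P/E-gate width
#'
#' The distance between the center of mass of the body-side gate residue
#' (A790 in the reference system) and the joint center of mass of the two
#' head-side loop residues (G1338 and A1339).
#'
#' @param model an [AtomicModel-class].
#' @param bodyRes selection for the body-side residue (default group tag
#'   "gate_A790").
#' @param loopRes selections for the loop residues (default tags
#'   "gate_G1338", "gate_A1339"), combined into one COM.
#' @return gate width, Angstrom.
#' @export
gateWidth <- function(model, bodyRes = "gate_A790",
                      loopRes = c("gate_G1338", "gate_A1339")) {
  comBody <- tryCatch(centerOfMass(model, bodyRes),
                      error = function(e)
                        stop("gateWidth: cannot resolve body residue (",
                             conditionMessage(e), ")"))
  idx <- unlist(lapply(loopRes, resolveSelection, model = model))
  if (!length(idx)) stop("gateWidth: cannot resolve loop residues")
  comLoop <- centerOfMass(model, idx)
  sqrt(sum((comBody - comLoop)^2))
}

#' Chasles screw-axis decomposition of a rigid displacement
#'
#' Extracts the best-fit rotation R and translation t mapping the reference
#' coordinates onto the displaced coordinates (unit-weight Kabsch), then
#' converts the pair to screw parameters: axis direction and angle from the
#' rotation vector, translation-along-axis t . u, and axis point from the
#' perpendicular component of t. The axis point returned is the point on
#' the axis closest to the reference selection's centroid. Displacements
#' rotating by less than `minAngle` take the pure-translation branch
#' (angle 0, axis along t).
#'
#' @param reference,displaced coordinate matrices (n x 3), equal sizes.
#' @param minAngle pure-translation threshold, degrees (default 0.1).
#' @return list(screw = [ScrewMotion-class], residual = RMSD of the rigid
#'   fit, transform = the underlying [RigidTransform-class]).
#' @export
screwDecompose <- function(reference, displaced, minAngle = 0.1) {
  stopifnot(nrow(reference) == nrow(displaced))
  k <- .kabsch(reference, displaced, rep(1, nrow(reference)))
  fitted <- sweep(reference %*% t(k$rotation), 2L, k$translation, "+")
  residual <- sqrt(mean(rowSums((fitted - displaced)^2)))
  aa <- rotationAngleAxis(k$rotation)
  t <- k$translation
  centroid <- colMeans(reference)
  if (aa$angle < minAngle) {
    nt <- sqrt(sum(t * t))
    dir <- if (nt > 0) t / nt else c(1, 0, 0)
    screw <- new("ScrewMotion", point = centroid, direction = dir,
                 angle = 0, translation = nt)
    return(list(screw = screw, residual = residual,
                transform = new("RigidTransform", rotation = k$rotation,
                                translation = t)))
  }
  u <- aa$axis
  d <- sum(t * u)
  tPerp <- t - d * u
  th <- aa$angle * pi / 180
  ## solve (I - R) p = tPerp for p in the plane perpendicular to u:
  ## p = tPerp/2 + (u x tPerp) / (2 tan(theta/2))
  p <- tPerp / 2 + .cross(u, tPerp) / (2 * tan(th / 2))
  ## canonical representative: point on the axis closest to the centroid
  p <- p + sum((centroid - p) * u) * u
  screw <- new("ScrewMotion", point = p, direction = u,
               angle = aa$angle, translation = d)
  list(screw = screw, residual = residual,
       transform = new("RigidTransform", rotation = k$rotation,
                       translation = t))
}

.cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Apply a screw motion to coordinates
#'
#' Rotates by the screw angle about the axis line and translates along the
#' axis: y = R (x - p) + p + d u.
#'
#' @param screw a [ScrewMotion-class].
#' @param coords coordinate matrix (n x 3).
#' @return displaced coordinates.
#' @export
screwApply <- function(screw, coords) {
  R <- rotationMatrix(screw@direction, screw@angle)
  sweep(sweep(coords, 2L, screw@point) %*% t(R), 2L,
        screw@point + screw@translation * screw@direction, "+")
}

#' Split a conformational change into internal and external motion
#'
#' The external (rigid-carry) motion is the displacement produced by
#' best-fitting structure A onto structure B over the whole selection; the
#' internal motion is the residual deformation after that fit. Per atom,
#' internal + external = total displacement exactly. Mean displacement
#' magnitudes are reported per requested sub-selection, mirroring
#' internal:external magnitude-ratio analyses of factor motion.
#'
#' @param modelA,modelB [AtomicModel-class] objects sharing atoms over the
#'   selections.
#' @param wholeSel selection defining the rigid fit (default all atoms).
#' @param subSels named list of sub-selections for magnitude reporting
#'   (default list(whole = wholeSel)).
#' @return list(internal, external, total = per-atom displacement matrices
#'   over `wholeSel`; magnitudes = data.frame(selection, internal,
#'   external, total) of mean displacement magnitudes; screw =
#'   [ScrewMotion-class] of the external motion).
#' @export
splitInternalExternal <- function(modelA, modelB, wholeSel = NULL,
                                  subSels = NULL) {
  ia <- resolveSelection(modelA, wholeSel)
  ib <- resolveSelection(modelB, wholeSel)
  stopifnot(length(ia) == length(ib))
  A <- modelA@coords[ia, , drop = FALSE]
  B <- modelB@coords[ib, , drop = FALSE]
  fit <- superpose(modelA, modelB, wholeSel)
  Afit <- applyTransform(fit, A)
  external <- Afit - A
  internal <- B - Afit
  total <- B - A
  if (is.null(subSels)) subSels <- list(whole = wholeSel)
  mag <- do.call(rbind, lapply(names(subSels), function(nm) {
    ii <- match(resolveSelection(modelA, subSels[[nm]]), ia)
    ii <- ii[!is.na(ii)]
    data.frame(selection = nm,
               internal = mean(sqrt(rowSums(internal[ii, , drop = FALSE]^2))),
               external = mean(sqrt(rowSums(external[ii, , drop = FALSE]^2))),
               total = mean(sqrt(rowSums(total[ii, , drop = FALSE]^2))))
  }))
  scr <- screwDecompose(A, Afit)
  list(internal = internal, external = external, total = total,
       magnitudes = mag, screw = scr$screw)
}
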