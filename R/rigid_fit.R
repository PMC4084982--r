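#' @include AllClasses.R AllGenerics.R structure_model.R density_maps.R
NULL

## Van der Waals radii (Angstrom) for the molecular-volume estimate.
.vdwRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               MG = 1.73, K = 2.75, "NA" = 2.27, CL = 1.75, ZN = 1.39,
               FE = 1.63, CA = 2.31, X = 1.70)

#' Estimate the molecular volume of a model
#'
#' Sum of atomic van der Waals sphere volumes times a packing factor, a
#' simple stand-in for the occupied molecular volume used to threshold
#' experimental maps.
#'
#' @param model an [AtomicModel-class].
#' @param packing packing factor (default 1.2).
#' @return volume in Angstrom^3.
#' @export
molecularVolume <- function(model, packing = 1.2) {
  key <- toupper(model@atoms$element)
  r <- .vdwRadii[key]
  r[is.na(r)] <- 1.7
  packing * sum(4 / 3 * pi * r^3)
}

#' Threshold a map to a target occupied volume
#'
#' Selects the highest-valued voxels whose cumulative volume best matches
#' the target molecular volume, reporting the threshold applied.
#'
#' @param map a [DensityMap-class].
#' @param targetVolume target occupied volume, Angstrom^3.
#' @return a [VoxelPointSet-class]. A zero target returns an empty set with
#'   threshold +Inf.
#' @export
thresholdToVolume <- function(map, targetVolume) {
  vox <- prod(map@spacing)
  if (targetVolume <= 0)
    return(new("VoxelPointSet", points = matrix(0, 0, 3),
               values = numeric(), threshold = Inf, voxelVolume = vox))
  pos <- which(map@values > 0)
  avail <- length(pos) * vox
  if (targetVolume > avail + vox / 2)
    stop(sprintf(
      "thresholdToVolume: target %.4g A^3 exceeds positive-voxel volume %.4g A^3",
      targetVolume, avail))
  nWant <- min(length(pos), max(1L, as.integer(round(targetVolume / vox))))
  v <- map@values[pos]
  ord <- order(v, pos, decreasing = TRUE)   # value desc, index ties stable
  take <- pos[ord[seq_len(nWant)]]
  ijk <- arrayInd(take, map@dims)
  pts <- sweep(sweep(ijk - 1, 2L, map@spacing, "*"), 2L, map@origin, "+")
  new("VoxelPointSet", points = pts, values = map@values[take],
      threshold = min(map@values[take]), voxelVolume = vox)
}

## Inertia frame of a weighted point cloud: COM + eigenvector matrix
## (columns, ascending moments).
.inertiaFrame <- function(pts, w) {
  com <- colSums(pts * w) / sum(w)
  x <- sweep(pts, 2L, com)
  r2 <- rowSums(x^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    I[a, b] <- sum(w * ((a == b) * r2 - x[, a] * x[, b]))
    I[b, a] <- I[a, b]
  }
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)
  list(com = com, axes = e$vectors[, ord, drop = FALSE],
       moments = e$values[ord])
}

#' Rigid fit of a model into a thresholded map by matching inertia moments
#'
#' Aligns the model's mass-weighted center of mass and principal axes to
#' those of the density-weighted voxel point set. Principal axes leave a
#' four-fold proper-rotation sign ambiguity; all four candidates are posed
#' and the one maximizing the CC of the posed model's synthetic map against
#' the target map is returned.
#'
#' @param model an [AtomicModel-class].
#' @param voxels a [VoxelPointSet-class] from [thresholdToVolume()].
#' @param map the target [DensityMap-class] used to score candidates.
#' @param resolution synthesis resolution for scoring (default the map's).
#' @param nNeighbor kernel truncation for scoring.
#' @return list(transform = [RigidTransform-class] posing the model into the
#'   map frame, cc = score of the winner, degenerate = logical).
#' @export
momentFit <- function(model, voxels, map, resolution = map@resolution,
                      nNeighbor = 4L) {
  if (nrow(voxels@points) < 4L)
    stop("momentFit: too few voxels in the point set")
  fv <- .inertiaFrame(voxels@points, voxels@values)
  fm <- .inertiaFrame(model@coords, model@masses)
  degenerate <- min(diff(fm$moments)) < 1e-9 * max(abs(fm$moments), 1) ||
    min(diff(fv$moments)) < 1e-9 * max(abs(fv$moments), 1)
  if (degenerate) {
    warning("momentFit: degenerate inertia tensor; center-of-mass alignment only")
    tr <- new("RigidTransform", rotation = diag(3),
              translation = fv$com - fm$com)
    posed <- transformModel(model, tr)
    cc <- correlationCoefficient(
      synthesizeMap(posed, .gridOf(map), resolution, nNeighbor,
                    onOutside = "skip"), map)
    return(list(transform = tr, cc = cc, degenerate = TRUE))
  }
  ## enumerate axis-sign assignments; exactly four give a proper rotation
  ## (which four depends on the handedness of the two eigenbases)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                c(-1, -1, -1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1))
  best <- NULL
  for (s in signs) {
    Av <- fv$axes %*% diag(s)
    R <- Av %*% t(fm$axes)
    if (det(R) < 0) next  # improper candidate
    tr <- new("RigidTransform", rotation = R,
              translation = as.numeric(fv$com - R %*% fm$com))
    posed <- transformModel(model, tr)
    cc <- correlationCoefficient(
      synthesizeMap(posed, .gridOf(map), resolution, nNeighbor,
                    onOutside = "skip"), map)
    if (is.null(best) || cc > best$cc)
      best <- list(transform = tr, cc = cc, degenerate = FALSE)
  }
  best
}

#' Local CC maximization over the six rigid degrees of freedom
#'
#' Deterministic coordinate-wise pattern search with shrinking steps
#' (translations 1.0 -> 0.05 A, rotations 2.0 -> 0.1 deg by halving).
#' Rotations are taken about the posed model's center of mass. The returned
#' CC never falls below the starting CC.
#'
#' @param model an [AtomicModel-class].
#' @param map target [DensityMap-class].
#' @param start starting [RigidTransform-class] (model -> map frame).
#' @param resolution synthesis resolution (default the map's).
#' @param nNeighbor kernel truncation.
#' @param stepTrans initial/final translation steps, Angstrom.
#' @param stepRot initial/final rotation steps, degrees.
#' @return list(transform, cc, ccStart, accepted = number of accepted
#'   moves, trace = CC after each sweep).
#' @export
refineRigidCC <- function(model, map, start = identityTransform(),
                          resolution = map@resolution, nNeighbor = 4L,
                          stepTrans = c(1.0, 0.05), stepRot = c(2.0, 0.1)) {
  score <- function(tr) {
    posed <- transformModel(model, tr)
    cc <- correlationCoefficient(
      synthesizeMap(posed, .gridOf(map), resolution, nNeighbor,
                    onOutside = "skip"), map)
    if (!is.finite(cc)) stop("refineRigidCC: non-finite CC during search")
    cc
  }
  cur <- start
  ccStart <- score(cur)
  ccCur <- ccStart
  accepted <- 0L
  trace <- numeric()
  sT <- stepTrans[1]; sR <- stepRot[1]
  axes <- diag(3)
  while (sT >= stepTrans[2] - 1e-12 || sR >= stepRot[2] - 1e-12) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      com <- colMeans(applyTransform(cur, model@coords))
      for (a in 1:3) for (sgn in c(1, -1)) {
        if (sT >= stepTrans[2] - 1e-12) {
          cand <- new("RigidTransform", rotation = cur@rotation,
                      translation = cur@translation + sgn * sT * axes[, a])
          cc <- score(cand)
          if (cc > ccCur + 1e-12) {
            cur <- cand; ccCur <- cc; improved <- TRUE
            accepted <- accepted + 1L
          }
        }
        if (sR >= stepRot[2] - 1e-12) {
          ## rotate about the current pose's COM: x' = Rd (x - com) + com
          Rd <- rotationMatrix(axes[, a], sgn * sR)
          cand <- new("RigidTransform", rotation = Rd %*% cur@rotation,
                      translation = as.numeric(Rd %*% cur@translation +
                                                 com - Rd %*% com))
          cc <- score(cand)
          if (cc > ccCur + 1e-12) {
            cur <- cand; ccCur <- cc; improved <- TRUE
            accepted <- accepted + 1L
          }
        }
      }
      trace <- c(trace, ccCur)
    }
    sT <- sT / 2; sR <- sR / 2
  }
  list(transform = cur, cc = ccCur, ccStart = ccStart,
       accepted = accepted, trace = trace)
}

#' Align an experimental map onto the frame of an atomic model
#'
#' The map-alignment pipeline: threshold the map to the model's molecular
#' volume, rigid-fit the model into the map by inertia moments, refine the
#' pose by CC ascent, then apply the inverse transform to the map itself and
#' regrid it (cloud-in-cell) onto a model-frame grid.
#'
#' @param map experimental [DensityMap-class] (clamped non-negative
#'   internally).
#' @param model reference [AtomicModel-class].
#' @param targetVolume occupied volume for thresholding (default
#'   [molecularVolume()] of the model).
#' @param resolution synthesis resolution (default the map's).
#' @param nNeighbor kernel truncation.
#' @param targetGrid output grid (default: map-spacing grid covering the
#'   model with a margin).
#' @return list(map = aligned [DensityMap-class], transform = model -> map
#'   transform found, cc = refined pose CC, threshold, ccTrace).
#' @export
alignMapToModel <- function(map, model, targetVolume = molecularVolume(model),
                            resolution = map@resolution, nNeighbor = 4L,
                            targetGrid = NULL) {
  map <- clampNegative(map)
  vox <- thresholdToVolume(map, targetVolume)
  mf <- momentFit(model, vox, map, resolution, nNeighbor)
  rf <- refineRigidCC(model, map, mf$transform, resolution, nNeighbor)
  if (is.null(targetGrid))
    targetGrid <- autoGrid(model, spacing = map@spacing,
                           margin = max(10L, nNeighbor + 6L))
  aligned <- cicRegrid(map, invertTransform(rf$transform), targetGrid,
                       clipTolerance = 1e-3)
  aligned@resolution <- resolution
  list(map = aligned, transform = rf$transform, cc = rf$cc,
       threshold = vox@threshold, ccTrace = rf$trace)
}
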