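#' @include AllClasses.R AllGenerics.R structure_model.R
NULL

## Default Gaussian width constant: sigma = resolution * sqrt(1/2) / pi makes
## the Fourier-space Gaussian fall to 1/e of its peak at spatial frequency
## 1/resolution ("resolution = half the width of a Gaussian in Fourier
## space"). The constant is one configurable parameter; CC and the fitting
## forces are self-consistent for any choice.
.defaultSigmaFactor <- sqrt(0.5) / pi

#' Construct a grid specification
#'
#' @param origin position of the first voxel center, Angstrom.
#' @param spacing voxel spacing per axis (scalar or length 3), Angstrom.
#' @param dims integer dims (nx, ny, nz).
#' @return list(origin, spacing, dims) used by [synthesizeMap()].
#' @export
gridSpec <- function(origin, spacing, dims) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  list(origin = as.numeric(origin), spacing = spacing,
       dims = as.integer(rep_len(dims, 3L)))
}

#' Grid covering a model with a margin
#'
#' @param model an [AtomicModel-class].
#' @param spacing voxel spacing, Angstrom.
#' @param margin margin in voxels added on every side (should be >=
#'   `nNeighbor` of the intended synthesis).
#' @return a grid spec (see [gridSpec()]).
#' @export
autoGrid <- function(model, spacing = 2, margin = 5L) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  lo <- apply(model@coords, 2L, min) - margin * spacing
  hi <- apply(model@coords, 2L, max) + margin * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  gridSpec(lo, spacing, dims)
}

.gridOf <- function(map) gridSpec(map@origin, map@spacing, map@dims)

.sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@dims, b@dims) &&
    max(abs(a@origin - b@origin)) < tol &&
    max(abs(a@spacing - b@spacing)) < tol
}

## Per-atom stencil bookkeeping: 1-based index window of the nNeighbor
## nearest grid planes on each side, per axis. Returns NULL margin violators.
.stencilIndex <- function(x, origin, spacing, dim, n) {
  f <- (x - origin) / spacing + 1  # fractional 1-based plane position
  iLow <- floor(f)
  list(first = iLow - n + 1L, last = iLow + n, frac = f)
}

#' Synthesize a simulated density map from atomic coordinates
#'
#' Each voxel value is the sum over atoms of atomic mass times a normalized
#' Gaussian kernel evaluated at the voxel-atom distance, truncated to the
#' `nNeighbor` nearest grid planes per axis in each direction (a (2n)^3
#' stencil). The kernel is normalized so that an untruncated atom
#' contributes its mass to the sum of voxel values.
#'
#' @param model an [AtomicModel-class].
#' @param grid a grid spec from [gridSpec()] / [autoGrid()].
#' @param resolution map resolution, Angstrom.
#' @param nNeighbor per-axis truncation half-width in grid planes (3 or 4
#'   in production; larger values are allowed for an effectively
#'   untruncated kernel).
#' @param sigmaFactor kernel width constant: sigma = resolution *
#'   sigmaFactor.
#' @param onOutside "error" (default) fails when any atom's stencil leaves
#'   the grid; "skip" silently drops such atoms (used when scoring trial
#'   rigid poses).
#' @return a [DensityMap-class].
#' @export
synthesizeMap <- function(model, grid, resolution, nNeighbor = 4L,
                          sigmaFactor = .defaultSigmaFactor,
                          onOutside = c("error", "skip")) {
  stopifnot(nNeighbor >= 1L, resolution > 0)
  onOutside <- match.arg(onOutside)
  n <- as.integer(nNeighbor)
  sigma <- resolution * sigmaFactor
  dims <- grid$dims
  sp <- grid$spacing
  org <- grid$origin
  st <- lapply(1:3, function(a)
    .stencilIndex(model@coords[, a], org[a], sp[a], dims[a], n))
  bad <- which(st[[1]]$first < 1L | st[[1]]$last > dims[1] |
               st[[2]]$first < 1L | st[[2]]$last > dims[2] |
               st[[3]]$first < 1L | st[[3]]$last > dims[3])
  if (length(bad) && onOutside == "error")
    stop("atoms outside grid margin: indices ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  norm <- prod(sp) / (2 * pi * sigma^2)^1.5
  vals <- array(0, dim = dims)
  off <- 0:(2L * n - 1L)
  for (i in setdiff(seq_len(nAtoms(model)), bad)) {
    ix <- st[[1]]$first[i] + off
    iy <- st[[2]]$first[i] + off
    iz <- st[[3]]$first[i] + off
    dx <- org[1] + (ix - 1) * sp[1] - model@coords[i, 1]
    dy <- org[2] + (iy - 1) * sp[2] - model@coords[i, 2]
    dz <- org[3] + (iz - 1) * sp[3] - model@coords[i, 3]
    wx <- exp(-dx^2 / (2 * sigma^2))
    wy <- exp(-dy^2 / (2 * sigma^2))
    wz <- exp(-dz^2 / (2 * sigma^2))
    vals[ix, iy, iz] <- vals[ix, iy, iz] +
      (model@masses[i] * norm) * (wx %o% wy %o% wz)
  }
  new("DensityMap", origin = org, spacing = sp, dims = dims,
      values = vals, resolution = resolution)
}

#' Real-space correlation coefficient of two maps
#'
#' Non-centered overlap form: CC = sum(e * s) / sqrt(sum(e^2) sum(s^2)).
#' The density-fitting objective is U_EM = -CC. The experimental map is
#' expected to be clamped non-negative first (see [clampNegative()]).
#'
#' @param sim,exp [DensityMap-class] objects on identical grids.
#' @return the correlation coefficient (scalar).
#' @export
correlationCoefficient <- function(sim, exp) {
  if (!.sameGrid(sim, exp))
    stop("correlationCoefficient: maps must share an identical grid")
  s <- sim@values; e <- exp@values
  B <- sum(e * e); C <- sum(s * s)
  if (B == 0 || C == 0)
    stop("correlationCoefficient undefined: a map is identically zero")
  sum(e * s) / sqrt(B * C)
}

#' Clamp negative voxel values to zero
#'
#' @param map a [DensityMap-class].
#' @return the map with values elementwise max(value, 0); metadata
#'   unchanged.
#' @export
clampNegative <- function(map) {
  map@values[map@values < 0] <- 0
  map
}

#' Analytic per-atom density-fitting forces
#'
#' Returns kEM * (-dU_EM/dr_i) with U_EM = -CC: the CC gradient is taken
#' with respect to the simulated voxel densities and chained to atomic
#' positions through the Gaussian spreading weights (the same truncated
#' stencil used by [synthesizeMap()]).
#'
#' @param model an [AtomicModel-class].
#' @param exp experimental/target [DensityMap-class] (clamped non-negative).
#' @param params an [EMFitParams-class]; `kEM` scales the returned forces.
#' @param sim optional precomputed simulated map of `model` on the same
#'   grid (saves one synthesis).
#' @param sigmaFactor kernel width constant (must match the synthesis).
#' @param onOutside "error" (default) or "skip": atoms whose stencil leaves
#'   the grid abort the computation or contribute no density and receive
#'   zero force.
#' @return list(forces = nAtoms x 3 matrix (kcal/mol/A when kEM carries
#'   energy units), cc = the correlation coefficient, sim = simulated map).
#' @export
emForce <- function(model, exp, params, sim = NULL,
                    sigmaFactor = .defaultSigmaFactor,
                    onOutside = c("error", "skip")) {
  onOutside <- match.arg(onOutside)
  stopifnot(is(params, "EMFitParams"))
  grid <- .gridOf(exp)
  if (is.null(sim))
    sim <- synthesizeMap(model, grid, params@resolution, params@nNeighbor,
                         sigmaFactor, onOutside = onOutside)
  else if (!.sameGrid(sim, exp))
    stop("emForce: sim map grid mismatch")
  s <- sim@values; e <- exp@values
  B <- sum(e * e); C <- sum(s * s)
  if (C == 0) stop("emForce: simulated density is identically zero")
  if (B == 0) stop("emForce: experimental density is identically zero")
  A <- sum(e * s)
  cc <- A / sqrt(B * C)
  dccds <- (e - (A / C) * s) / sqrt(B * C)
  sigma <- params@resolution * sigmaFactor
  n <- params@nNeighbor
  dims <- grid$dims; sp <- grid$spacing; org <- grid$origin
  norm <- prod(sp) / (2 * pi * sigma^2)^1.5
  st <- lapply(1:3, function(a)
    .stencilIndex(model@coords[, a], org[a], sp[a], dims[a], n))
  bad <- which(st[[1]]$first < 1L | st[[1]]$last > dims[1] |
               st[[2]]$first < 1L | st[[2]]$last > dims[2] |
               st[[3]]$first < 1L | st[[3]]$last > dims[3])
  off <- 0:(2L * n - 1L)
  forces <- matrix(0, nAtoms(model), 3L)
  for (i in setdiff(seq_len(nAtoms(model)), bad)) {
    ix <- st[[1]]$first[i] + off
    iy <- st[[2]]$first[i] + off
    iz <- st[[3]]$first[i] + off
    dx <- org[1] + (ix - 1) * sp[1] - model@coords[i, 1]
    dy <- org[2] + (iy - 1) * sp[2] - model@coords[i, 2]
    dz <- org[3] + (iz - 1) * sp[3] - model@coords[i, 3]
    wx <- exp(-dx^2 / (2 * sigma^2))
    wy <- exp(-dy^2 / (2 * sigma^2))
    wz <- exp(-dz^2 / (2 * sigma^2))
    g <- dccds[ix, iy, iz]
    pref <- model@masses[i] * norm / sigma^2
    forces[i, 1] <- pref * sum(g * ((wx * dx) %o% wy %o% wz))
    forces[i, 2] <- pref * sum(g * (wx %o% (wy * dy) %o% wz))
    forces[i, 3] <- pref * sum(g * (wx %o% wy %o% (wz * dz)))
  }
  list(forces = params@kEM * forces, cc = cc, sim = sim)
}

#' Energy weight making EM forces a stated fraction of structural forces
#'
#' Returns kEM such that the mean per-atom magnitude of kEM * F_EM equals
#' wEM times the mean per-atom magnitude of the structural forces: at
#' wEM = 1 the average density-fitting force matches the average structural
#' force.
#'
#' @param emForces nAtoms x 3 matrix of unscaled density forces.
#' @param strForces nAtoms x 3 matrix of structural forces.
#' @param wEM dimensionless weight (>= 0).
#' @return scalar kEM.
#' @export
scaleWeight <- function(emForces, strForces, wEM) {
  stopifnot(wEM >= 0, nrow(emForces) > 0, nrow(strForces) > 0)
  if (wEM == 0) return(0)
  mStr <- mean(sqrt(rowSums(strForces^2)))
  mEM <- mean(sqrt(rowSums(emForces^2)))
  if (mEM == 0) stop("scaleWeight: all EM forces are zero")
  if (mStr <= 0) stop("scaleWeight: mean structural force must be > 0")
  wEM * mStr / mEM
}

#' Cloud-in-cell regridding of a density map
#'
#' Applies a rigid transform to every source voxel position and shares each
#' voxel's value among the 8 surrounding target voxels with trilinear
#' weights. Total density is conserved.
#'
#' @param map source [DensityMap-class].
#' @param transform a [RigidTransform-class] applied to voxel positions.
#' @param target target grid spec (see [gridSpec()]).
#' @param clipTolerance maximum fraction of total density allowed to fall
#'   outside the target grid; exceeding it is an error with a clipped-mass
#'   report, below it the clipped voxels are dropped with a warning
#'   (default 0: any clipping errors).
#' @return a [DensityMap-class] on the target grid.
#' @export
cicRegrid <- function(map, transform, target, clipTolerance = 0) {
  dims <- map@dims
  nz <- which(map@values != 0)
  out <- array(0, dim = target$dims)
  if (length(nz)) {
    ijk <- arrayInd(nz, dims)
    pos <- sweep(sweep(ijk - 1, 2L, map@spacing, "*"), 2L, map@origin, "+")
    pos <- applyTransform(transform, pos)
    f <- sweep(sweep(pos, 2L, target$origin), 2L, target$spacing, "/") + 1
    ## snap near-integer fractions so an identity regrid is exact
    fr <- f - round(f)
    f[abs(fr) < 1e-9] <- round(f[abs(fr) < 1e-9])
    i0 <- floor(f)
    t3 <- f - i0
    inside <- i0[, 1] >= 1 & i0[, 1] + 1 <= target$dims[1] &
              i0[, 2] >= 1 & i0[, 2] + 1 <= target$dims[2] &
              i0[, 3] >= 1 & i0[, 3] + 1 <= target$dims[3]
    ## voxels landing exactly on the far boundary plane have zero weight
    ## beyond it; treat them as inside by clamping
    atEdge <- !inside &
      i0[, 1] >= 1 & i0[, 1] <= target$dims[1] &
      i0[, 2] >= 1 & i0[, 2] <= target$dims[2] &
      i0[, 3] >= 1 & i0[, 3] <= target$dims[3] &
      (i0[, 1] < target$dims[1] | t3[, 1] == 0) &
      (i0[, 2] < target$dims[2] | t3[, 2] == 0) &
      (i0[, 3] < target$dims[3] | t3[, 3] == 0)
    if (any(atEdge)) {
      shift <- function(a) {
        hit <- atEdge & i0[, a] == target$dims[a]
        i0[hit, a] <<- i0[hit, a] - 1L
        t3[hit, a] <<- 1
      }
      shift(1); shift(2); shift(3)
      inside <- inside | atEdge
    }
    if (!all(inside)) {
      clipped <- sum(map@values[nz][!inside])
      frac <- abs(clipped) / max(abs(sum(map@values)), .Machine$double.xmin)
      if (frac > clipTolerance)
        stop(sprintf(
          "cicRegrid: transformed support exceeds target grid (%d voxels, clipped mass %.6g)",
          sum(!inside), clipped))
      warning(sprintf("cicRegrid: dropped %d voxels outside the target grid (mass %.3g)",
                      sum(!inside), clipped))
      nz <- nz[inside]
      i0 <- i0[inside, , drop = FALSE]
      t3 <- t3[inside, , drop = FALSE]
    }
    v <- map@values[nz]
    nd <- target$dims
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) t3[, 1] else 1 - t3[, 1]) *
           (if (cy) t3[, 2] else 1 - t3[, 2]) *
           (if (cz) t3[, 3] else 1 - t3[, 3])
      keep <- w > 0
      if (!any(keep)) next
      lin <- (i0[keep, 1] + cx) +
             (i0[keep, 2] + cy - 1L) * nd[1] +
             (i0[keep, 3] + cz - 1L) * nd[1] * nd[2]
      acc <- rowsum(v[keep] * w[keep], lin)
      out[as.integer(rownames(acc))] <- out[as.integer(rownames(acc))] +
        as.numeric(acc)
    }
  }
  new("DensityMap", origin = as.numeric(target$origin),
      spacing = as.numeric(target$spacing),
      dims = as.integer(target$dims), values = out,
      resolution = map@resolution)
}

## ---------------------------------------------------------------------------
## MRC2014 I/O (MODE 2, 32-bit float; axis order normalized on read)
## ---------------------------------------------------------------------------

#' Write a density map as MRC2014 (MODE 2)
#'
#' @param map a [DensityMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- map@dims
  vals <- as.numeric(map@values)
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(c(d * map@spacing, 90, 90, 90)), con, size = 4L,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con, size = 4L,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4L, endian = "little")
  writeBin(integer(25L), con, size = 4L, endian = "little")      # extra
  writeBin(as.numeric(map@origin), con, size = 4L, endian = "little")
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)               # machst
  writeBin(as.numeric(stats::sd(vals)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")                # nlabl
  writeBin(raw(800L), con)
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC2014 density map (MODE 2)
#'
#' Axis order is normalized to X-fastest; the voxel spacing comes from the
#' cell dimensions and sampling counts. When the ORIGIN record is all zero,
#' the start indices supply the origin.
#'
#' @param path MRC file path.
#' @param resolution nominal resolution to attach, Angstrom (not stored in
#'   the format).
#' @return a [DensityMap-class].
#' @export
readMRC <- function(path, resolution = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  cell <- readBin(con, "numeric", n = 6L, size = 4L, endian = "little")
  axmap <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  stats3 <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  readBin(con, "integer", n = 25L, size = 4L, endian = "little")
  orig <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readChar(con, nchars = 4L, useBytes = TRUE)
  readBin(con, "raw", n = 4L)
  readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
  readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  readBin(con, "raw", n = 800L)
  nxyz <- ints1[1:3]
  mode <- ints1[4]
  if (mode != 2L) stop("readMRC: only MODE 2 (float32) is supported")
  nstart <- ints1[5:7]
  mxyz <- ints1[8:10]
  vals <- readBin(con, "numeric", n = prod(nxyz), size = 4L,
                  endian = "little")
  arr <- array(vals, dim = nxyz)
  spacing <- cell[1:3] / mxyz
  if (!identical(axmap, c(1L, 2L, 3L))) {
    perm <- order(axmap)        # file axis holding crystal axis 1, 2, 3
    arr <- aperm(arr, perm)
    nxyz <- nxyz[perm]
    nstart <- nstart[perm]
  }
  if (all(orig == 0)) orig <- nstart * spacing
  new("DensityMap", origin = as.numeric(orig),
      spacing = as.numeric(spacing), dims = as.integer(dim(arr)),
      values = arr, resolution = resolution)
}

#' Construct EM-fitting parameters
#'
#' @param resolution map resolution, Angstrom.
#' @param nNeighbor 3 or 4 grid planes per axis per direction.
#' @param wEM dimensionless fitting weight.
#' @param kEM energy weight; usually derived via [scaleWeight()].
#' @return an [EMFitParams-class].
#' @export
emFitParams <- function(resolution, nNeighbor = 4L, wEM = 1, kEM = 1) {
  new("EMFitParams", resolution = as.numeric(resolution),
      nNeighbor = as.integer(nNeighbor), wEM = as.numeric(wEM),
      kEM = as.numeric(kEM))
}
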