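#' @include AllClasses.R
NULL

#' Number of atoms in a model
#' @param x an [AtomicModel-class].
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom coordinates
#' @param x an [AtomicModel-class].
#' @return numeric matrix (nAtoms x 3), Angstrom.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Replace atom coordinates
#' @param x an [AtomicModel-class].
#' @param value numeric matrix (nAtoms x 3).
#' @return the modified object.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Atom masses
#' @param x an [AtomicModel-class].
#' @return numeric vector, amu.
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' Group tags
#' @param x an [AtomicModel-class].
#' @return named list of integer atom-index vectors.
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' Replace group tags
#' @param x an [AtomicModel-class].
#' @param value named list of integer atom-index vectors.
#' @return the modified object.
#' @export
setGeneric("groups<-", function(x, value) standardGeneric("groups<-"))

#' Voxel values of a density map
#' @param x a [DensityMap-class].
#' @return 3-D numeric array.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Apply a rigid transform
#' @param x a [RigidTransform-class].
#' @param coords numeric matrix (n x 3) of positions, Angstrom.
#' @return transformed coordinate matrix.
#' @export
setGeneric("applyTransform",
           function(x, coords) standardGeneric("applyTransform"))

setMethod("nAtoms", "AtomicModel", function(x) nrow(x@coords))
setMethod("coords", "AtomicModel", function(x) x@coords)
setMethod("coords<-", "AtomicModel", function(x, value) {
  stopifnot(is.matrix(value), all(dim(value) == dim(x@coords)))
  x@coords <- value
  validObject(x)
  x
})
setMethod("masses", "AtomicModel", function(x) x@masses)
setMethod("groups", "AtomicModel", function(x) x@groups)
setMethod("groups<-", "AtomicModel", function(x, value) {
  x@groups <- value
  validObject(x)
  x
})
setMethod("mapValues", "DensityMap", function(x) x@values)

setMethod("applyTransform", "RigidTransform", function(x, coords) {
  stopifnot(ncol(coords) == 3L)
  sweep(coords %*% t(x@rotation), 2L, x@translation, "+")
})

setMethod("show", "AtomicModel", function(object) {
  cat("AtomicModel with", nAtoms(object), "atoms,",
      length(object@groups), "group tags\n")
  if (length(object@groups))
    cat("  groups:", paste(utils::head(names(object@groups), 8L),
                           collapse = ", "),
        if (length(object@groups) > 8L) "..." else "", "\n")
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap %dx%dx%d, spacing %.2f/%.2f/%.2f A, resolution %.2f A\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@resolution))
  cat(sprintf("  values in [%.4g, %.4g], sum %.6g\n",
              min(object@values), max(object@values), sum(object@values)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- tryCatch(rotationAngleAxis(object@rotation)$angle, error = function(e) NA)
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) A\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "ScrewMotion", function(object) {
  cat(sprintf("ScrewMotion: %.3f deg about (%.3f, %.3f, %.3f), %.3f A along axis\n",
              object@angle, object@direction[1], object@direction[2],
              object@direction[3], object@translation))
})

setMethod("show", "WhamSolution", function(object) {
  cat(sprintf("WhamSolution: %d windows, %d samples, converged in %d iterations (max dF %.2e)\n",
              length(object@F), length(object@logWeights),
              object@convergence$iterations, object@convergence$maxDeltaF))
})

setMethod("show", "UmbrellaDataset", function(object) {
  ns <- vapply(object@windows, function(w) dim(w$samples)[1], integer(1))
  cat(sprintf("UmbrellaDataset: %d windows, %d samples total, T = %.1f K\n",
              length(object@windows), sum(ns), object@temperature))
})
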