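#' @include AllClasses.R AllGenerics.R
NULL

## Built-in element masses (amu). Selections and density synthesis weight by
## mass, so an unknown element must fail loudly rather than default to zero.
.elementMasses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  "NA" = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904,
  X = 12.011  # generic bead used by the synthetic toy models
)

#' Look up atomic masses for element symbols
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @param massOverride optional named numeric vector supplying masses for
#'   elements absent from the built-in table.
#' @return numeric vector of masses in amu.
#' @export
elementMass <- function(elements, massOverride = NULL) {
  key <- toupper(trimws(elements))
  tab <- .elementMasses
  if (!is.null(massOverride)) {
    ov <- massOverride
    names(ov) <- toupper(names(ov))
    tab[names(ov)] <- ov
  }
  m <- unname(tab[key])
  if (anyNA(m)) {
    bad <- sort(unique(key[is.na(m)]))
    stop("unknown element(s) with no mass override: ",
         paste(bad, collapse = ", "))
  }
  m
}

#' Construct an AtomicModel from raw pieces
#'
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param element character vector of element symbols (recycled if length 1).
#' @param name atom names; default element symbols.
#' @param resno residue numbers; default 1:n.
#' @param resname residue names; default "BEA".
#' @param chain chain ids; default "A".
#' @param masses explicit masses (amu); default looked up from `element`.
#' @param groups named list of integer atom-index vectors.
#' @param massOverride passed to [elementMass()].
#' @return an [AtomicModel-class].
#' @export
atomicModel <- function(coords, element = "X", name = NULL, resno = NULL,
                        resname = "BEA", chain = "A", masses = NULL,
                        groups = list(), massOverride = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  element <- rep_len(as.character(element), n)
  if (is.null(name)) name <- element
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(masses)) masses <- elementMass(element, massOverride)
  atoms <- data.frame(
    name = rep_len(as.character(name), n),
    element = element,
    resno = rep_len(as.integer(resno), n),
    resname = rep_len(as.character(resname), n),
    chain = rep_len(as.character(chain), n),
    stringsAsFactors = FALSE
  )
  new("AtomicModel", atoms = atoms, coords = coords,
      masses = as.numeric(masses), groups = groups)
}

## Guess the element symbol from a PDB atom name when the element column is
## blank (common in minimal files): strip digits/primes, try two letters then
## one.
.guessElement <- function(name, known = names(.elementMasses)) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1L, 2L)
  one <- substr(nm, 1L, 1L)
  ifelse(two %in% known, two, one)
}

#' Read an atomic model from a PDB file
#'
#' One atom per ATOM/HETATM record. Multi-model files contribute MODEL 1
#' only. Alternate locations keep altloc ' ' or 'A'. Masses come from the
#' built-in element table; an element that cannot be resolved raises an
#' error unless `massOverride` supplies it.
#'
#' @param path PDB file path.
#' @param massOverride named numeric vector of masses for non-table elements.
#' @return an [AtomicModel-class].
#' @export
readPDB <- function(path, massOverride = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keep, , drop = FALSE]
  el <- trimws(ifelse(is.na(at$elesy) | at$elesy == "", "", at$elesy))
  el[el == ""] <- .guessElement(at$elety[el == ""])
  atomicModel(
    coords = cbind(at$x, at$y, at$z),
    element = el,
    name = trimws(at$elety),
    resno = at$resno,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    massOverride = massOverride
  )
}

#' Write an atomic model to a PDB file
#'
#' @param model an [AtomicModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(model, path) {
  at <- model@atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(model@coords)),
    resno = at$resno, resid = at$resname, chain = at$chain,
    elety = at$name, elesy = at$element
  )
  invisible(path)
}

## ---------------------------------------------------------------------------
## Selections
## ---------------------------------------------------------------------------

#' Build a leaf selection
#'
#' Non-empty predicates combine by intersection: `selection(chain = "A",
#' resno = 790)` selects chain A residue 790.
#'
#' @param chain chain ids to match (empty = any).
#' @param resno residue numbers to match (empty = any).
#' @param name atom names to match (empty = any).
#' @param group group-tag names to match (selects tagged atoms).
#' @return a [SelectionSpec-class].
#' @export
selection <- function(chain = character(), resno = integer(),
                      name = character(), group = character()) {
  new("SelectionSpec", chain = as.character(chain),
      resno = as.integer(resno), name = as.character(name),
      group = as.character(group), op = "leaf", parts = list())
}

#' Union of selections
#' @param ... SelectionSpec objects.
#' @return a [SelectionSpec-class].
#' @export
selUnion <- function(...)
  new("SelectionSpec", op = "union", parts = list(...))

#' Intersection of selections
#' @param ... SelectionSpec objects.
#' @return a [SelectionSpec-class].
#' @export
selIntersect <- function(...)
  new("SelectionSpec", op = "intersect", parts = list(...))

#' Resolve a selection against a model
#'
#' @param model an [AtomicModel-class].
#' @param sel a [SelectionSpec-class], a group name, or an integer index
#'   vector (taken as-is). `NULL` selects all atoms.
#' @return sorted unique integer atom indices.
#' @export
resolveSelection <- function(model, sel = NULL) {
  if (is.null(sel)) return(seq_len(nAtoms(model)))
  if (is.numeric(sel)) return(sort(unique(as.integer(sel))))
  if (is.character(sel)) {
    if (!all(sel %in% names(model@groups)))
      stop("unknown group tag(s): ",
           paste(setdiff(sel, names(model@groups)), collapse = ", "))
    return(sort(unique(unlist(model@groups[sel], use.names = FALSE))))
  }
  stopifnot(is(sel, "SelectionSpec"))
  if (sel@op == "union") {
    idx <- unlist(lapply(sel@parts, resolveSelection, model = model))
    return(sort(unique(idx)))
  }
  if (sel@op == "intersect") {
    idxs <- lapply(sel@parts, resolveSelection, model = model)
    return(sort(Reduce(intersect, idxs)))
  }
  at <- model@atoms
  keep <- rep(TRUE, nrow(at))
  if (length(sel@chain)) keep <- keep & at$chain %in% sel@chain
  if (length(sel@resno)) keep <- keep & at$resno %in% sel@resno
  if (length(sel@name)) keep <- keep & at$name %in% sel@name
  if (length(sel@group)) {
    gidx <- resolveSelection(model, sel@group)
    gmask <- rep(FALSE, nrow(at))
    gmask[gidx] <- TRUE
    keep <- keep & gmask
  }
  which(keep)
}

## ---------------------------------------------------------------------------
## Centers of mass, superposition, principal axes
## ---------------------------------------------------------------------------

#' Mass-weighted center of mass of a selection
#'
#' @param model an [AtomicModel-class].
#' @param sel selection (see [resolveSelection()]); `NULL` = all atoms.
#' @return length-3 numeric, Angstrom.
#' @export
centerOfMass <- function(model, sel = NULL) {
  idx <- resolveSelection(model, sel)
  if (!length(idx)) stop("empty selection in centerOfMass")
  m <- model@masses[idx]
  colSums(model@coords[idx, , drop = FALSE] * m) / sum(m)
}

#' Centers of mass of all tagged groups
#'
#' @param model an [AtomicModel-class].
#' @param groupNames which groups (default all, in tag order).
#' @return matrix (nGroups x 3) with group names as rownames.
#' @export
groupCenters <- function(model, groupNames = names(model@groups)) {
  out <- t(vapply(groupNames,
                  function(g) centerOfMass(model, g), numeric(3)))
  rownames(out) <- groupNames
  out
}

## Weighted Kabsch: returns list(rotation, translation) mapping x -> y
## (y ~ R x + t) minimizing the weighted RMSD.
.kabsch <- function(x, y, w) {
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  xc <- sweep(x, 2L, cx)
  yc <- sweep(y, 2L, cy)
  H <- t(xc * w) %*% yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(cy - R %*% cx))
}

#' Mass-weighted least-squares rigid superposition (Kabsch)
#'
#' Returns the proper rigid transform minimizing the mass-weighted RMSD of
#' the mobile selection onto the reference selection. Applying the result to
#' the mobile model's coordinates yields the fitted pose.
#'
#' @param mobile,reference [AtomicModel-class] objects.
#' @param sel selection resolved in both models (must give equal counts).
#' @param selRef selection for the reference when it differs from `sel`.
#' @param weights "mass" (default) or "unit".
#' @return a [RigidTransform-class].
#' @export
superpose <- function(mobile, reference, sel = NULL, selRef = sel,
                      weights = c("mass", "unit")) {
  weights <- match.arg(weights)
  im <- resolveSelection(mobile, sel)
  ir <- resolveSelection(reference, selRef)
  if (length(im) != length(ir))
    stop("selections resolve to different atom counts (",
         length(im), " vs ", length(ir), ")")
  if (length(im) < 3L) stop("superposition needs at least 3 atoms")
  x <- mobile@coords[im, , drop = FALSE]
  y <- reference@coords[ir, , drop = FALSE]
  w <- if (weights == "mass") mobile@masses[im] else rep(1, length(im))
  ## collinearity check on the dominant spread of the mobile selection
  xc <- sweep(x, 2L, colSums(x * (w / sum(w))))
  ev <- eigen(t(xc * w) %*% xc, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-9 * max(ev[1], 1))
    stop("degenerate superposition: selected atoms are (near-)collinear")
  k <- .kabsch(x, y, w)
  new("RigidTransform", rotation = k$rotation, translation = k$translation)
}

#' RMSD between two models over a selection
#'
#' @param a,b [AtomicModel-class] objects.
#' @param sel selection resolved in both (equal counts).
#' @param weights "mass" or "unit".
#' @return RMSD in Angstrom.
#' @export
rmsdModels <- function(a, b, sel = NULL, weights = c("mass", "unit")) {
  weights <- match.arg(weights)
  ia <- resolveSelection(a, sel)
  ib <- resolveSelection(b, sel)
  stopifnot(length(ia) == length(ib))
  w <- if (weights == "mass") a@masses[ia] else rep(1, length(ia))
  d2 <- rowSums((a@coords[ia, , drop = FALSE] -
                 b@coords[ib, , drop = FALSE])^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Compose two rigid transforms (apply `a` after `b`)
#' @param a,b [RigidTransform-class] objects.
#' @return a [RigidTransform-class] equal to `a %then% b` on coordinates:
#'   `x -> a(b(x))`.
#' @export
composeTransform <- function(a, b) {
  new("RigidTransform",
      rotation = a@rotation %*% b@rotation,
      translation = as.numeric(a@rotation %*% b@translation + a@translation))
}

#' Invert a rigid transform
#' @param x a [RigidTransform-class].
#' @return the inverse transform.
#' @export
invertTransform <- function(x) {
  Rt <- t(x@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% x@translation))
}

#' Identity transform
#' @return a [RigidTransform-class] with identity rotation, zero translation.
#' @export
identityTransform <- function()
  new("RigidTransform", rotation = diag(3), translation = numeric(3))

#' Apply a rigid transform to a model
#' @param model an [AtomicModel-class].
#' @param transform a [RigidTransform-class].
#' @return the transformed model (atom count and identities preserved).
#' @export
transformModel <- function(model, transform) {
  coords(model) <- applyTransform(transform, model@coords)
  model
}

#' Mass-weighted principal axes of a selection
#'
#' Eigenvectors of the mass-weighted inertia tensor about the selection's
#' center of mass, columns ordered by increasing moment (axis 1 = smallest
#' moment, the long axis of an elongated body). Each axis is sign-oriented
#' to a positive dot product with the corresponding column of
#' `referenceDirections` (principal axes are otherwise sign-ambiguous).
#'
#' @param model an [AtomicModel-class].
#' @param sel selection; `NULL` = all atoms.
#' @param referenceDirections 3x3 matrix of orientation references per axis
#'   (default identity).
#' @return list(axes = 3x3 matrix with axes in columns, moments = numeric 3,
#'   degenerate = logical flag set when two moments agree within 1e-9
#'   relative).
#' @export
principalAxes <- function(model, sel = NULL, referenceDirections = diag(3)) {
  idx <- resolveSelection(model, sel)
  if (length(idx) < 3L) stop("principalAxes needs at least 3 atoms")
  m <- model@masses[idx]
  x <- sweep(model@coords[idx, , drop = FALSE], 2L,
             colSums(model@coords[idx, , drop = FALSE] * m) / sum(m))
  r2 <- rowSums(x^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    I[a, b] <- sum(m * ((a == b) * r2 - x[, a] * x[, b]))
    I[b, a] <- I[a, b]
  }
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)
  axes <- e$vectors[, ord, drop = FALSE]
  moments <- e$values[ord]
  for (j in 1:3) {
    s <- sum(axes[, j] * referenceDirections[, j])
    if (s < 0) axes[, j] <- -axes[, j]
  }
  scale <- max(abs(moments), 1)
  degenerate <- min(diff(sort(moments))) < 1e-9 * scale
  if (degenerate)
    warning("principalAxes: (near-)degenerate inertia moments")
  list(axes = axes, moments = moments, degenerate = degenerate)
}

#' Convert a rotation matrix to axis-angle form
#'
#' @param R 3x3 proper rotation matrix.
#' @return list(angle = degrees in [0, 180], axis = unit 3-vector; axis is
#'   arbitrary for angle 0).
#' @export
rotationAngleAxis <- function(R) {
  tr <- sum(diag(R))
  cosTheta <- min(1, max(-1, (tr - 1) / 2))
  theta <- acos(cosTheta)
  if (theta < 1e-12)
    return(list(angle = 0, axis = c(1, 0, 0)))
  if (abs(pi - theta) < 1e-6) {
    ## near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    k <- which.max(axis)
    if (axis[k] > 0) {
      axis <- B[, k] / axis[k]
      axis <- axis / sqrt(sum(axis^2))
    } else axis <- c(1, 0, 0)
  } else {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    axis <- v / (2 * sin(theta))
    axis <- axis / sqrt(sum(axis^2))
  }
  list(angle = theta * 180 / pi, axis = axis)
}

#' Rotation matrix about an axis
#'
#' @param axis 3-vector (normalized internally).
#' @param angle rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
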