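#' @include AllClasses.R AllGenerics.R structure_model.R density_maps.R
#' @include sampling_engine.R geometry_analysis.R
NULL

#' Specification of the synthetic two-body ratchet assembly
#'
#' @param nLarge,nSmall,nHead,nTRNA bead counts (large body, small body,
#'   head, each tRNA-like group).
#' @param ratchetAmplitude small-subunit rotation between the POST-like and
#'   PRE-like endpoints, degrees.
#' @param headAmplitude head swivel of the INT-like endpoint, degrees.
#' @param tRNATravel tRNA-group travel between endpoints, Angstrom.
#' @param gateOpening gate-width increase from POST-like to PRE-like,
#'   Angstrom.
#' @param nGroups approximate number of umbrella groups.
#' @param kIntra,kInter intra-/inter-group spring constants, kcal/mol/A^2.
#' @param barrier collective bistability barrier between the POST-like and
#'   PRE-like conformations, kcal/mol; 0 disables the double-well term and
#'   leaves a single POST basin.
#' @param kConfine condensed-phase confinement, kcal/mol/A^2: immobile
#'   beads are anchored at their POST positions and mobile beads confined
#'   perpendicular to their POST-to-PRE displacement lines (standing in
#'   for the packing of the solvated assembly, which the bead network
#'   alone cannot supply).
#' @param seed RNG seed; the model is bitwise-reproducible from
#'   (spec, seed).
#' @return a [ToyRibosomeSpec-class].
#' @export
toyRibosomeSpec <- function(nLarge = 80L, nSmall = 50L, nHead = 24L,
                            nTRNA = 6L, ratchetAmplitude = 6,
                            headAmplitude = 8, tRNATravel = 4,
                            gateOpening = 6, nGroups = 10L, kIntra = 2,
                            kInter = 0.02, barrier = 6, kConfine = 0.3,
                            seed = 1L) {
  new("ToyRibosomeSpec", nLarge = as.integer(nLarge),
      nSmall = as.integer(nSmall), nHead = as.integer(nHead),
      nTRNA = as.integer(nTRNA), ratchetAmplitude = ratchetAmplitude,
      headAmplitude = headAmplitude, tRNATravel = tRNATravel,
      gateOpening = gateOpening, nGroups = as.integer(nGroups),
      kIntra = kIntra, kInter = kInter, barrier = barrier,
      kConfine = kConfine, seed = as.integer(seed))
}

## beads quasi-uniform in an ellipsoid (rejection sampling)
.blob <- function(n, center, semi) {
  out <- matrix(NA_real_, n, 3L)
  got <- 0L
  while (got < n) {
    cand <- matrix(stats::runif(3L * 2L * (n - got), -1, 1), ncol = 3L)
    keep <- rowSums(cand^2) <= 1
    take <- min(sum(keep), n - got)
    if (take > 0) {
      out[got + seq_len(take), ] <- cand[which(keep)[seq_len(take)], ,
                                         drop = FALSE]
      got <- got + take
    }
  }
  sweep(out * rep(semi, each = n), 2L, center, "+")
}

#' Build the synthetic ratchet assembly and its endpoint conformations
#'
#' Emulates the coupled structure the downstream analysis assumes: a large
#' body, a small body carrying a swivelling head, two mobile tRNA-like bead
#' groups between the bodies, and a three-residue gate analogue (a body
#' bead cluster versus a two-cluster head loop). The tRNA travel direction
#' is +y (the P-to-E direction) and the intersubunit ratchet axis is -x
#' (small-to-large COM direction). Three endpoints are returned: POST-like
#' (base), INT-like (head swiveled by `headAmplitude` about the plane
#' normal), and PRE-like (small subunit rotated by `ratchetAmplitude` about
#' the ratchet axis, tRNA groups displaced by `tRNATravel` along +y, gate
#' opened by `gateOpening`).
#'
#' The structural potential bonds each bead to its nearest neighbours
#' within its umbrella group (stiff) and links neighbouring groups through
#' their closest bead pairs (soft), so the assembly holds its shape while
#' the subunits can reorient.
#'
#' @param spec a [ToyRibosomeSpec-class].
#' @return list(model = POST-like [AtomicModel-class] with group tags,
#'   potential = [ToyPotential-class], endpoints = list(POST, INT, PRE) of
#'   models, eTRNA, eRatchet, anchors = list(rPI, rEI)).
#' @export
makeToyRibosome <- function(spec) {
  set.seed(spec@seed)
  cLarge <- c(0, 0, 0)
  cSmall <- c(24, 0, 0)
  cHead <- c(24, 0, 11)
  large <- .blob(spec@nLarge, cLarge, c(13, 11, 11))
  small <- .blob(spec@nSmall, cSmall, c(9, 8, 7))
  head <- .blob(spec@nHead, cHead, c(4, 8, 2.5))  # long axis along +y
  tP <- .blob(spec@nTRNA, c(16, -3, 5), c(1.2, 1.2, 1.2))
  tE <- .blob(spec@nTRNA, c(16, 3, 5), c(1.2, 1.2, 1.2))
  g790 <- .blob(3L, c(20, 1, 5), c(0.6, 0.6, 0.6))
  g1338 <- .blob(3L, c(22, 2.5, 8.5), c(0.6, 0.6, 0.6))
  g1339 <- .blob(3L, c(22, 3.5, 8.5), c(0.6, 0.6, 0.6))
  coords <- rbind(large, small, head, tP, tE, g790, g1338, g1339)
  n <- nrow(coords)
  unit <- rep(c("large", "smallbody", "head", "tRNA_P", "tRNA_E",
                "gate_A790", "gate_G1338", "gate_A1339"),
              c(spec@nLarge, spec@nSmall, spec@nHead, spec@nTRNA,
                spec@nTRNA, 3L, 3L, 3L))
  resno <- seq_len(n)
  resno[unit == "gate_A790"] <- 790L
  resno[unit == "gate_G1338"] <- 1338L
  resno[unit == "gate_A1339"] <- 1339L
  ## structural tags; gate body cluster belongs to the small body, the loop
  ## clusters to the head (so the swivel carries them)
  tags <- list(
    large = which(unit == "large"),
    smallbody = which(unit %in% c("smallbody", "gate_A790")),
    head = which(unit %in% c("head", "gate_G1338", "gate_A1339")),
    tRNA_P = which(unit == "tRNA_P"),
    tRNA_E = which(unit == "tRNA_E"),
    gate_A790 = which(unit == "gate_A790"),
    gate_G1338 = which(unit == "gate_G1338"),
    gate_A1339 = which(unit == "gate_A1339")
  )
  tags$small <- sort(c(tags$smallbody, tags$head))
  ## umbrella groups: proportional split of the structural units
  units <- list(large = tags$large, smallbody = tags$smallbody,
                head = tags$head, tRNA_P = tags$tRNA_P,
                tRNA_E = tags$tRNA_E)
  alloc <- stats::setNames(pmax(1L, round(spec@nGroups * lengths(units) / n)),
                           names(units))
  ug <- list()
  for (uNm in names(units)) {
    idx <- units[[uNm]]
    parts <- if (alloc[[uNm]] < 2L) list(idx)
             else split(idx, cut(seq_along(idx), alloc[[uNm]],
                                 labels = FALSE))
    for (p in parts) ug[[sprintf("grp%02d", length(ug) + 1L)]] <- p
  }
  model <- atomicModel(coords, element = "X", resno = resno,
                       resname = substr(toupper(unit), 1, 3),
                       chain = "A", groups = c(ug, tags))
  ## ---- endpoints -------------------------------------------------------
  ## ratchet axis: small-body COM toward large-body COM (the rigid small
  ## body is the measured selection; the head carries the deformable gate)
  eRatchet <- centerOfMass(model, "large") - centerOfMass(model, "smallbody")
  eRatchet <- eRatchet / sqrt(sum(eRatchet^2))
  eTRNA <- c(0, 1, 0)
  planeNormal <- .cross(eTRNA, eRatchet)
  planeNormal <- planeNormal / sqrt(sum(planeNormal^2))
  rotAbout <- function(xy, idx, axis, angle, center) {
    R <- rotationMatrix(axis, angle)
    xy[idx, ] <- sweep(sweep(xy[idx, , drop = FALSE], 2L, center) %*% t(R),
                       2L, center, "+")
    xy
  }
  ## INT: head swivel about the plane normal through the head COM
  cINT <- coords
  cHeadCom <- centerOfMass(model, "head")
  ## negative right-handed rotation about the plane normal = clockwise =
  ## positive measured head angle
  cINT <- rotAbout(cINT, tags$head, planeNormal, -spec@headAmplitude,
                   cHeadCom)
  ## PRE: whole small subunit rotated about the ratchet axis through its
  ## COM; tRNA groups travel along +y; gate opened to the stated width
  cPRE <- coords
  comSmall <- centerOfMass(model, "small")
  cPRE <- rotAbout(cPRE, tags$small, eRatchet, spec@ratchetAmplitude,
                   comSmall)
  trnaIdx <- c(tags$tRNA_P, tags$tRNA_E)
  cPRE[trnaIdx, ] <- sweep(cPRE[trnaIdx, , drop = FALSE], 2L,
                           spec@tRNATravel * eTRNA, "+")
  mkModel <- function(xy) { m <- model; coords(m) <- xy; m }
  widthPOST <- gateWidth(model)
  mPRE <- mkModel(cPRE)
  comBody <- centerOfMass(mPRE, "gate_A790")
  loopIdx <- c(tags$gate_G1338, tags$gate_A1339)
  comLoop <- colSums(cPRE[loopIdx, , drop = FALSE] *
                       model@masses[loopIdx]) / sum(model@masses[loopIdx])
  dirOut <- comLoop - comBody
  dirOut <- dirOut / sqrt(sum(dirOut^2))
  wantWidth <- widthPOST + spec@gateOpening
  haveWidth <- gateWidth(mPRE)
  cPRE[loopIdx, ] <- sweep(cPRE[loopIdx, , drop = FALSE], 2L,
                           (wantWidth - haveWidth) * dirOut, "+")
  mPRE <- mkModel(cPRE)
  mINT <- mkModel(cINT)
  ## ---- potential -------------------------------------------------------
  bonds <- list()
  for (g in ug) {
    if (length(g) < 2L) next
    sub <- coords[g, , drop = FALSE]
    D <- as.matrix(stats::dist(sub))
    for (a in seq_along(g)) {
      nb <- order(D[a, ])[2:min(4L, length(g))]
      for (b in nb) if (g[a] < g[b])
        bonds[[length(bonds) + 1L]] <-
          c(g[a], g[b], spec@kIntra, D[a, b])
    }
  }
  gc <- t(vapply(ug, function(g) colMeans(coords[g, , drop = FALSE]),
                 numeric(3)))
  for (a in seq_along(ug)) for (b in seq_along(ug)) {
    if (a >= b) next
    if (sqrt(sum((gc[a, ] - gc[b, ])^2)) > 18) next
    ia <- ug[[a]]; ib <- ug[[b]]
    D <- outer(seq_along(ia), seq_along(ib), function(p, q)
      sqrt(rowSums((coords[ia[p], , drop = FALSE] -
                    coords[ib[q], , drop = FALSE])^2)))
    hit <- arrayInd(which.min(D), dim(D))
    iHit <- ia[hit[1]]; jHit <- ib[hit[2]]
    ## rest length midway between the endpoint geometries so neither
    ## conformation is favoured by the soft inter-group links
    r0 <- (D[hit] + sqrt(sum((cPRE[iHit, ] - cPRE[jHit, ])^2))) / 2
    bonds[[length(bonds) + 1L]] <- c(iHit, jHit, spec@kInter, r0)
  }
  bondDf <- as.data.frame(do.call(rbind, bonds))
  names(bondDf) <- c("i", "j", "k", "r0")
  bondDf <- unique(bondDf)
  ## every bond is given its midpoint rest length between the endpoint
  ## geometries, and bonds spanning parts that move relative to each other
  ## (> 1 A change) are softened: neither endpoint conformation is strained
  dPOST <- sqrt(rowSums((coords[bondDf$j, ] - coords[bondDf$i, ])^2))
  dPRE <- sqrt(rowSums((cPRE[bondDf$j, ] - cPRE[bondDf$i, ])^2))
  bondDf$r0 <- (dPOST + dPRE) / 2
  bondDf$k[abs(dPOST - dPRE) > 1] <- spec@kInter
  ## bistable term: per mobile bead a double-well along its POST -> PRE
  ## displacement with minima at both endpoint positions, so the assembly
  ## has two metastable conformations separated by a stated collective
  ## barrier
  fields <- list()
  disp <- cPRE - coords
  mobile <- which(sqrt(rowSums(disp^2)) > 0.5)
  fixed <- setdiff(seq_len(n), mobile)
  kC <- spec@kConfine
  if (length(fixed) && kC > 0) {
    pF <- coords[fixed, , drop = FALSE]
    fields[[length(fields) + 1L]] <- list(atoms = fixed, fun = function(xy) {
      d <- xy - pF
      list(energy = kC * sum(d * d), forces = -2 * kC * d)
    })
  }
  if (length(mobile)) {
    p0 <- coords[mobile, , drop = FALSE]
    tlen <- sqrt(rowSums(disp[mobile, , drop = FALSE]^2))
    uhat <- disp[mobile, , drop = FALSE] / tlen
    ## barrier distributed with equal per-bead well curvature
    ## (h_i proportional to t_i^2), summing to the stated collective value
    h <- if (spec@barrier > 0) spec@barrier * tlen^2 / sum(tlen^2) else
      rep(0, length(mobile))
    fields[[length(fields) + 1L]] <- list(atoms = mobile, fun = function(xy) {
      rel <- xy - p0
      s <- rowSums(rel * uhat)
      dperp <- rel - s * uhat
      E <- kC * sum(dperp * dperp)
      F <- -2 * kC * dperp
      if (spec@barrier > 0) {
        pref <- 16 * h / tlen^4
        E <- E + sum(pref * s^2 * (s - tlen)^2)
        dUds <- pref * 2 * s * (s - tlen) * (2 * s - tlen)
        F <- F - dUds * uhat
      }
      list(energy = E, forces = F)
    })
  }
  potential <- toyPotential(bonds = bondDf, fields = fields)
  list(model = model, potential = potential,
       endpoints = list(POST = model, INT = mINT, PRE = mPRE),
       eTRNA = eTRNA, eRatchet = eRatchet,
       anchors = list(rPI = centerOfMass(model, "tRNA_P"),
                      rEI = centerOfMass(model, "tRNA_E")))
}

#' Synthesize density maps of the endpoint conformations
#'
#' One map per endpoint on a common grid covering all endpoints, optionally
#' with additive Gaussian voxel noise (then clamped non-negative) to
#' emulate experimental maps.
#'
#' @param endpoints list of [AtomicModel-class] endpoint conformations.
#' @param resolution map resolution, Angstrom.
#' @param spacing voxel spacing, Angstrom.
#' @param noiseSd additive Gaussian noise SD (0 = noise-free).
#' @param nNeighbor kernel truncation.
#' @param seed RNG seed for the noise.
#' @param margin grid margin in voxels around the endpoint ensemble.
#' @return named list of [DensityMap-class] objects.
#' @export
makeStateMaps <- function(endpoints, resolution = 8, spacing = 2,
                          noiseSd = 0, nNeighbor = 4L, seed = 1L,
                          margin = nNeighbor + 4L) {
  allxy <- do.call(rbind, lapply(endpoints, coords))
  spacing <- rep_len(spacing, 3L)
  lo <- apply(allxy, 2L, min) - margin * spacing
  hi <- apply(allxy, 2L, max) + margin * spacing
  grid <- gridSpec(lo, spacing, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  set.seed(seed)
  out <- lapply(endpoints, function(m) {
    mp <- synthesizeMap(m, grid, resolution, nNeighbor)
    if (noiseSd > 0) {
      mp@values <- mp@values +
        array(stats::rnorm(prod(mp@dims), sd = noiseSd), dim = mp@dims)
      mp <- clampNegative(mp)
    }
    mp
  })
  names(out) <- names(endpoints)
  out
}

#' Analytic reference landscape with closed-form free energy
#'
#' Kinds: `"harmonic"` (params `k`: U = k x^2), `"doublewell"` (params
#' `a`, `b`: U = a (x^2 - b^2)^2, barrier a b^4 between minima at x = -b
#' and +b) and `"separable2d"` (params `kx`, `ky`: U = kx x^2 + ky y^2).
#' For a single coordinate the free energy along x equals the potential up
#' to an additive constant.
#'
#' @param kind landscape kind.
#' @param params named numeric parameters.
#' @param temperature Kelvin.
#' @return a [ReferenceLandscape-class].
#' @export
makeReferenceLandscape <- function(kind = c("harmonic", "doublewell",
                                            "separable2d"),
                                   params, temperature = 300) {
  kind <- match.arg(kind)
  need <- switch(kind, harmonic = "k", doublewell = c("a", "b"),
                 separable2d = c("kx", "ky"))
  if (!all(need %in% names(params)))
    stop("makeReferenceLandscape: params must contain ",
         paste(need, collapse = ", "))
  new("ReferenceLandscape", kind = kind,
      params = params[need], temperature = temperature)
}

#' Evaluate a reference landscape's potential
#'
#' @param landscape a [ReferenceLandscape-class].
#' @param x coordinate(s), Angstrom.
#' @param y second coordinate for 2-D kinds.
#' @return potential energy, kcal/mol.
#' @export
landscapePotential <- function(landscape, x, y = 0) {
  p <- landscape@params
  switch(landscape@kind,
    harmonic = p[["k"]] * x^2,
    doublewell = p[["a"]] * (x^2 - p[["b"]]^2)^2,
    separable2d = p[["kx"]] * x^2 + p[["ky"]] * y^2)
}

#' Closed-form free-energy profile of a reference landscape
#'
#' For one particle on U(x), F(x) = U(x) up to an additive constant; the
#' returned values are shifted so the minimum over the supplied grid is
#' zero.
#'
#' @param landscape a [ReferenceLandscape-class].
#' @param x evaluation grid, Angstrom.
#' @return free energies, kcal/mol (min 0 on the grid).
#' @export
landscapeFreeEnergy <- function(landscape, x) {
  u <- landscapePotential(landscape, x)
  u - min(u)
}

#' Barrier height of a double-well reference landscape
#'
#' @param landscape a [ReferenceLandscape-class] of kind "doublewell".
#' @return barrier a b^4, kcal/mol.
#' @export
landscapeBarrier <- function(landscape) {
  stopifnot(landscape@kind == "doublewell")
  p <- landscape@params
  p[["a"]] * p[["b"]]^4
}

#' Exact Monte-Carlo umbrella dataset on an analytic landscape
#'
#' Metropolis sampling from each window's biased Boltzmann density
#' exp(-(U(x) + V_j(x))/kT) with a stated burn-in and thinning,
#' reproducible by seed. The umbrella coordinate is embedded as the x
#' component of a single 3-D group coordinate (y = z = 0), so the dataset
#' feeds [whamSolve()] unchanged. Bias form "k" means V = k (x - c)^2.
#'
#' @param landscape a [ReferenceLandscape-class] (1-D kinds).
#' @param centers numeric vector of window centers, Angstrom.
#' @param biasK bias force constant(s), kcal/mol/A^2 (recycled).
#' @param nPerWindow samples per window.
#' @param seed integer seed.
#' @param burnin discarded initial iterations per window.
#' @param thin keep every `thin`-th iteration.
#' @param proposalSd Metropolis proposal SD, Angstrom.
#' @param form bias functional form tag ("k" or "k/2").
#' @return an [UmbrellaDataset-class].
#' @export
generateUmbrellaDataset <- function(landscape, centers, biasK = 2,
                                    nPerWindow = 2000L, seed = 1L,
                                    burnin = 500L, thin = 5L,
                                    proposalSd = 0.3, form = "k") {
  stopifnot(landscape@kind %in% c("harmonic", "doublewell"))
  set.seed(seed)
  kT <- kBoltzmann * landscape@temperature
  biasK <- rep_len(biasK, length(centers))
  fac <- if (form == "k") 1 else 0.5
  wins <- vector("list", length(centers))
  for (j in seq_along(centers)) {
    cj <- centers[j]; kj <- biasK[j]
    utot <- function(x)
      landscapePotential(landscape, x) + fac * kj * (x - cj)^2
    x <- cj
    ux <- utot(x)
    nIter <- burnin + nPerWindow * thin
    keep <- numeric(nPerWindow)
    got <- 0L
    acc <- 0L
    prop <- stats::rnorm(nIter, sd = proposalSd)
    unif <- stats::runif(nIter)
    for (it in seq_len(nIter)) {
      xn <- x + prop[it]
      un <- utot(xn)
      if (un <= ux || unif[it] < exp(-(un - ux) / kT)) {
        x <- xn; ux <- un; acc <- acc + 1L
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        got <- got + 1L
        keep[got] <- x
      }
    }
    if (acc / nIter < 0.01)
      stop(sprintf(
        "generateUmbrellaDataset: acceptance rate %.2f%% in window %d; widen the proposal",
        100 * acc / nIter, j))
    samples <- array(0, c(nPerWindow, 1L, 3L))
    samples[, 1L, 1L] <- keep
    wins[[j]] <- list(samples = samples,
                      centers = matrix(c(cj, 0, 0), 1L, 3L),
                      k = kj, form = form)
  }
  new("UmbrellaDataset", windows = wins,
      temperature = landscape@temperature)
}
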