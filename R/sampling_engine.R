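#' @include AllClasses.R AllGenerics.R structure_model.R density_maps.R
NULL

## Unit system: kcal/mol, Angstrom, ps, amu.
## 1 kcal/mol = 418.4 amu A^2/ps^2, so accelerations are F * .fScale / m.
.fScale <- 418.4
#' Boltzmann constant in kcal/mol/K
#' @export
kBoltzmann <- 1.987204e-3

## ---------------------------------------------------------------------------
## Restraints
## ---------------------------------------------------------------------------

#' @rdname restraints
#' @exportClass ComHarmonicRestraint
setClass("ComHarmonicRestraint",
  representation(atoms = "integer", center = "numeric", k = "numeric",
                 form = "character", scale = "numeric"),
  prototype(form = "k", scale = 1))

#' @rdname restraints
#' @exportClass PositionalRestraint
setClass("PositionalRestraint",
  representation(atoms = "integer", ref = "matrix", k = "numeric",
                 scale = "numeric"),
  prototype(scale = 1))

#' @rdname restraints
#' @exportClass FlatBottomRestraint
setClass("FlatBottomRestraint",
  representation(i = "integer", j = "integer", d0 = "numeric",
                 tol = "numeric", k = "numeric", scale = "numeric"),
  prototype(tol = 0.1, scale = 1))

#' @rdname restraints
#' @exportClass RmsdCapRestraint
setClass("RmsdCapRestraint",
  representation(atoms = "integer", ref = "matrix", limit = "numeric",
                 k = "numeric", scale = "numeric"),
  prototype(limit = 1, scale = 1))

#' Restraint constructors
#'
#' The restraint zoo of the windowed protocol. Two harmonic conventions are
#' used deliberately: umbrella/COM restraints are V = k |dR|^2 with k in
#' kcal/mol/A^2 (so the protocol's canonical k = 1.0 gives each restrained
#' center of mass an RMSF of ~0.2 A at 300 K), while steering restraints are
#' V = k/2 |dR|^2 with k quoted in pN/A (so force = k * displacement);
#' convert with [convertForceConstant()]. The functional form is recorded
#' with the restraint and consumed as-is by WHAM.
#'
#' * `comRestraint(atoms, center, k, form)`: harmonic restraint on the
#'   mass-weighted center of mass of `atoms`.
#' * `positionalRestraint(atoms, ref, k)`: per-atom harmonic tether
#'   V = k sum |r - ref|^2.
#' * `flatBottomRestraint(i, j, d0, tol, k)`: pair-distance restraint that
#'   is identically zero while |d - d0| <= tol (default tolerance 0.1 A,
#'   the hydrogen-bond dead zone) and quadratic outside.
#' * `rmsdRestraint(atoms, ref, limit, k)`: zero while the (no-refit,
#'   unit-weight) RMSD to `ref` is <= limit (default 1 A), quadratic
#'   outside.
#'
#' @param atoms integer atom indices.
#' @param center length-3 numeric target, Angstrom.
#' @param k force constant (kcal/mol/A^2).
#' @param form "k" (V = k |d|^2) or "k/2" (V = k/2 |d|^2).
#' @param ref reference coordinate matrix for the selected atoms.
#' @param i,j atom indices of the restrained pair.
#' @param d0 ideal distance, Angstrom.
#' @param tol dead-zone half-width, Angstrom.
#' @param limit RMSD dead-zone limit, Angstrom.
#' @return a restraint object.
#' @name restraints
NULL

#' @rdname restraints
#' @export
comRestraint <- function(atoms, center, k = 1, form = c("k", "k/2")) {
  form <- match.arg(form)
  new("ComHarmonicRestraint", atoms = as.integer(atoms),
      center = as.numeric(center), k = k, form = form, scale = 1)
}

#' @rdname restraints
#' @export
positionalRestraint <- function(atoms, ref, k = 1)
  new("PositionalRestraint", atoms = as.integer(atoms),
      ref = as.matrix(ref), k = k, scale = 1)

#' @rdname restraints
#' @export
flatBottomRestraint <- function(i, j, d0, tol = 0.1, k = 10)
  new("FlatBottomRestraint", i = as.integer(i), j = as.integer(j),
      d0 = d0, tol = tol, k = k, scale = 1)

#' @rdname restraints
#' @export
rmsdRestraint <- function(atoms, ref, limit = 1, k = 10)
  new("RmsdCapRestraint", atoms = as.integer(atoms), ref = as.matrix(ref),
      limit = limit, k = k, scale = 1)

#' Energy and forces of a restraint
#'
#' @param x a restraint object.
#' @param coords full coordinate matrix (n x 3), Angstrom.
#' @param massv full mass vector, amu.
#' @return list(energy, atoms = affected indices, forces = matrix for those
#'   atoms).
#' @export
setGeneric("restraintEnergyForce",
           function(x, coords, massv) standardGeneric("restraintEnergyForce"))

setMethod("restraintEnergyForce", "ComHarmonicRestraint",
  function(x, coords, massv) {
    m <- massv[x@atoms]
    M <- sum(m)
    com <- colSums(coords[x@atoms, , drop = FALSE] * m) / M
    d <- com - x@center
    fac <- if (x@form == "k") 2 else 1   # dV/d|d| coefficient over k
    E <- x@scale * (x@k / (if (x@form == "k") 1 else 2)) * sum(d * d)
    g <- x@scale * fac * x@k * d          # dV/dcom
    F <- -outer(m / M, g)
    list(energy = E, atoms = x@atoms, forces = F)
  })

setMethod("restraintEnergyForce", "PositionalRestraint",
  function(x, coords, massv) {
    d <- coords[x@atoms, , drop = FALSE] - x@ref
    E <- x@scale * x@k * sum(d * d)
    list(energy = E, atoms = x@atoms, forces = -2 * x@scale * x@k * d)
  })

setMethod("restraintEnergyForce", "FlatBottomRestraint",
  function(x, coords, massv) {
    v <- coords[x@j, ] - coords[x@i, ]
    d <- sqrt(sum(v * v))
    exc <- abs(d - x@d0) - x@tol
    if (exc <= 0 || d == 0)
      return(list(energy = 0, atoms = c(x@i, x@j),
                  forces = matrix(0, 2, 3)))
    E <- x@scale * x@k * exc^2
    dVdd <- 2 * x@scale * x@k * exc * sign(d - x@d0)
    u <- v / d
    Fi <- dVdd * u       # -dV/dri = -dVdd * (-u) = dVdd * u
    list(energy = E, atoms = c(x@i, x@j), forces = rbind(Fi, -Fi))
  })

setMethod("restraintEnergyForce", "RmsdCapRestraint",
  function(x, coords, massv) {
    d <- coords[x@atoms, , drop = FALSE] - x@ref
    n <- length(x@atoms)
    r <- sqrt(sum(d * d) / n)
    if (r <= x@limit)
      return(list(energy = 0, atoms = x@atoms,
                  forces = matrix(0, n, 3)))
    E <- x@scale * x@k * (r - x@limit)^2
    F <- -2 * x@scale * x@k * (r - x@limit) * d / (n * r)
    list(energy = E, atoms = x@atoms, forces = F)
  })

## ---------------------------------------------------------------------------
## Toy potential
## ---------------------------------------------------------------------------

#' Construct a toy structural potential
#'
#' @param bonds data.frame(i, j, k, r0): harmonic bonds V = k (r - r0)^2.
#' @param repulsion data.frame(i, j, eps, sigma): V = eps (sigma/r)^12.
#' @param fields list of external terms, each list(atoms, fun) where
#'   fun(coordsSub) returns list(energy, forces).
#' @return a [ToyPotential-class].
#' @export
toyPotential <- function(bonds = NULL, repulsion = NULL, fields = list()) {
  p <- new("ToyPotential")
  if (!is.null(bonds)) p@bonds <- bonds
  if (!is.null(repulsion)) p@repulsion <- repulsion
  p@fields <- fields
  p
}

#' Energy and forces of a toy potential
#'
#' @param potential a [ToyPotential-class].
#' @param coords coordinate matrix (n x 3), Angstrom.
#' @return list(energy = kcal/mol, forces = n x 3 matrix, kcal/mol/A).
#' @export
potentialEnergyForce <- function(potential, coords) {
  n <- nrow(coords)
  F <- matrix(0, n, 3L)
  E <- 0
  b <- potential@bonds
  if (nrow(b)) {
    dv <- coords[b$j, , drop = FALSE] - coords[b$i, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    dr <- r - b$r0
    E <- E + sum(b$k * dr * dr)
    fmag <- 2 * b$k * dr / pmax(r, 1e-12)   # force on i along +dv
    fv <- dv * fmag
    F <- F + .accumRows(fv, b$i, n) - .accumRows(fv, b$j, n)
  }
  rp <- potential@repulsion
  if (nrow(rp)) {
    dv <- coords[rp$j, , drop = FALSE] - coords[rp$i, , drop = FALSE]
    r <- pmax(sqrt(rowSums(dv * dv)), 1e-9)
    sr <- (rp$sigma / r)^12
    E <- E + sum(rp$eps * sr)
    fmag <- -12 * rp$eps * sr / (r * r)     # on i along +dv (repulsive)
    fv <- dv * fmag
    F <- F + .accumRows(fv, rp$i, n) - .accumRows(fv, rp$j, n)
  }
  for (fl in potential@fields) {
    ef <- fl$fun(coords[fl$atoms, , drop = FALSE])
    E <- E + ef$energy
    F[fl$atoms, ] <- F[fl$atoms, ] + ef$forces
  }
  if (!is.finite(E) || !all(is.finite(F)))
    stop("toy potential produced a non-finite energy or force")
  list(energy = E, forces = F)
}

.accumRows <- function(v, idx, n) {
  out <- matrix(0, n, 3L)
  acc <- rowsum(v, idx)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

## Total force/energy from potential + restraints (+ optional fixed EM
## force added in by the integrator).
.totalEF <- function(potential, restraints, coords, massv) {
  ef <- potentialEnergyForce(potential, coords)
  for (r in restraints) {
    re <- restraintEnergyForce(r, coords, massv)
    ef$energy <- ef$energy + re$energy
    ef$forces[re$atoms, ] <- ef$forces[re$atoms, ] + re$forces
  }
  ef
}

## ---------------------------------------------------------------------------
## Langevin dynamics (BAOAB) and minimization
## ---------------------------------------------------------------------------

#' Run Langevin dynamics (BAOAB discretization)
#'
#' NVT Langevin dynamics on a toy potential with restraints and an optional
#' density-fitting force. The EM force is treated as a slow force: it is
#' recomputed every `emTerm$stride` steps and held constant in between, with
#' its energy weight re-derived from the instantaneous structural forces via
#' [scaleWeight()] at each recomputation. With `friction = 0` the
#' integrator reduces to velocity Verlet (no thermostat, no noise).
#'
#' @param coords starting coordinates (n x 3), Angstrom.
#' @param massv masses, amu.
#' @param potential a [ToyPotential-class].
#' @param restraints list of restraint objects.
#' @param nSteps number of steps.
#' @param dt time step, ps.
#' @param temperature Kelvin.
#' @param friction Langevin friction, 1/ps.
#' @param velocities starting velocities (default: Maxwell-Boltzmann draw,
#'   or zeros when friction = 0 and temperature = 0).
#' @param emTerm optional list(map = target [DensityMap-class], params =
#'   [EMFitParams-class], stride = steps between recomputations, exclude =
#'   atom indices whose EM force is zeroed).
#' @param groups optional list of atom-index vectors whose mass-weighted
#'   COMs are recorded.
#' @param recordEvery record stride in steps (0 = no recording).
#' @param rampDown indices into `restraints` whose scale is ramped linearly
#'   from 1 to 0 over the run.
#' @param seed optional integer seed (set once at entry).
#' @return list(coords, velocities, energy = trace of potential+restraint
#'   energy at records, kinetic = kinetic-energy trace, series = record
#'   array (nRec x nGroups x 3) when groups given, cc = last CC when emTerm
#'   given, emForces = last scaled EM force matrix).
#' @export
runLangevin <- function(coords, massv, potential, restraints = list(),
                        nSteps, dt = 0.01, temperature = 300, friction = 5,
                        velocities = NULL, emTerm = NULL, groups = NULL,
                        recordEvery = 0L, rampDown = integer(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(coords)
  kT <- kBoltzmann * temperature
  if (is.null(velocities)) {
    velocities <- if (temperature > 0)
      matrix(stats::rnorm(3 * n, sd = rep(sqrt(kT * .fScale / massv), 3)),
             n, 3)
    else matrix(0, n, 3)
  }
  c1 <- exp(-friction * dt)
  c2v <- sqrt(pmax(kT * .fScale / massv * (1 - c1^2), 0))
  invm <- .fScale / massv
  emF <- matrix(0, n, 3)
  cc <- NA_real_
  scales0 <- vapply(restraints, function(r) r@scale, numeric(1))
  ef <- .totalEF(potential, restraints, coords, massv)
  updateEM <- function(coords, strForces) {
    mdl <- atomicModel(coords, masses = massv,
                       element = rep("X", n))
    raw <- emForce(mdl, emTerm$map,
                   emFitParams(emTerm$params@resolution,
                               emTerm$params@nNeighbor,
                               emTerm$params@wEM, kEM = 1),
                   onOutside = "skip")
    f <- raw$forces
    if (length(emTerm$exclude)) f[emTerm$exclude, ] <- 0
    kEM <- tryCatch(scaleWeight(f, strForces, emTerm$params@wEM),
                    error = function(e) 0)
    list(forces = kEM * f, cc = raw$cc)
  }
  if (!is.null(emTerm)) {
    up <- updateEM(coords, ef$forces)
    emF <- up$forces
    cc <- up$cc
  }
  nRec <- if (recordEvery > 0) nSteps %/% recordEvery else 0L
  series <- if (!is.null(groups) && nRec > 0)
    array(NA_real_, c(nRec, length(groups), 3L)) else NULL
  eTrace <- if (nRec > 0) numeric(nRec) else numeric()
  kTrace <- if (nRec > 0) numeric(nRec) else numeric()
  iRec <- 0L
  gm <- if (!is.null(groups))
    lapply(groups, function(g) massv[g] / sum(massv[g])) else NULL
  F <- ef$forces + emF
  for (step in seq_len(nSteps)) {
    if (length(rampDown)) {
      s <- 1 - step / nSteps
      for (ri in rampDown) restraints[[ri]]@scale <- scales0[ri] * s
    }
    velocities <- velocities + (0.5 * dt) * F * invm
    coords <- coords + (0.5 * dt) * velocities
    if (friction > 0 && temperature > 0) {
      velocities <- c1 * velocities +
        matrix(stats::rnorm(3 * n, sd = rep(c2v, 3)), n, 3)
    } else if (friction > 0) {
      velocities <- c1 * velocities
    }
    coords <- coords + (0.5 * dt) * velocities
    ef <- .totalEF(potential, restraints, coords, massv)
    if (!is.null(emTerm) && step %% emTerm$stride == 0L) {
      up <- updateEM(coords, ef$forces)
      emF <- up$forces
      cc <- up$cc
    }
    F <- ef$forces + emF
    velocities <- velocities + (0.5 * dt) * F * invm
    if (recordEvery > 0 && step %% recordEvery == 0L) {
      iRec <- iRec + 1L
      eTrace[iRec] <- ef$energy
      kTrace[iRec] <- 0.5 * sum(massv * rowSums(velocities^2)) / .fScale
      if (!is.null(series))
        for (g in seq_along(groups))
          series[iRec, g, ] <- colSums(coords[groups[[g]], , drop = FALSE] *
                                         gm[[g]])
    }
  }
  list(coords = coords, velocities = velocities, energy = eTrace,
       kinetic = kTrace, series = series, cc = cc, emForces = emF)
}

#' Steepest-descent energy minimization with backtracking
#'
#' @param coords starting coordinates (n x 3).
#' @param potential a [ToyPotential-class].
#' @param restraints list of restraint objects.
#' @param massv masses (needed by COM restraints); default unit.
#' @param maxSteps maximum accepted steps.
#' @param tol gradient-norm tolerance (max |F| component, kcal/mol/A).
#' @param step0 initial step scale, Angstrom per unit force.
#' @return list(coords, energy = trace of accepted energies, converged,
#'   flag = "ok" or "linesearch" when the search stalled).
#' @export
minimizeEnergy <- function(coords, potential, restraints = list(),
                           massv = rep(1, nrow(coords)), maxSteps = 1000L,
                           tol = 1e-6, step0 = 0.1) {
  ef <- .totalEF(potential, restraints, coords, massv)
  energies <- ef$energy
  alpha <- step0
  flag <- "ok"
  for (s in seq_len(maxSteps)) {
    fmax <- max(abs(ef$forces))
    if (fmax < tol) break
    accepted <- FALSE
    for (try in 1:30) {
      cand <- coords + alpha * ef$forces / fmax
      efC <- .totalEF(potential, restraints, cand, massv)
      if (efC$energy <= ef$energy) {
        coords <- cand
        ef <- efC
        energies <- c(energies, ef$energy)
        alpha <- alpha * 1.2
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { flag <- "linesearch"; break }
  }
  list(coords = coords, energy = energies,
       converged = max(abs(ef$forces)) < tol, flag = flag)
}

## ---------------------------------------------------------------------------
## The window protocol
## ---------------------------------------------------------------------------

#' Adapt the density-fitting weight from realized COM displacement
#'
#' Multiplicative controller keeping the per-window displacement of every
#' umbrella coordinate within the cap (0.60 A in the reference protocol):
#' the weight doubles when the max shift stayed below cap/2, halves when it
#' exceeded the cap, and is clipped to the schedule bounds.
#'
#' @param prevShift per-group COM displacements of the last fitting phase,
#'   Angstrom.
#' @param wEM current weight.
#' @param cap displacement cap, Angstrom (default 0.60).
#' @param bounds schedule bounds (default the reference schedule,
#'   1e-7 .. 1e-4).
#' @return the adapted weight.
#' @export
adaptWEM <- function(prevShift, wEM, cap = 0.60, bounds = c(1e-7, 1e-4)) {
  mx <- max(prevShift)
  if (mx > cap) wEM <- wEM * 0.5
  else if (mx < cap / 2) wEM <- wEM * 2
  min(max(wEM, bounds[1]), bounds[2])
}

#' Run one window of the EM-fitting / umbrella-sampling protocol
#'
#' One cycle: (1) EM-fitting phase with the density force (and optional
#' steering and auxiliary restraints) driving the structure toward the
#' target map, retried with a halved weight when any group COM moves more
#' than `cap`; (2) umbrella centers are set to the current group COMs; (3)
#' equilibration with the bias on and transient restraints ramped off; (4)
#' sampling of the umbrella coordinates. The next window restarts from the
#' configuration a fraction `restartFraction` into the sampling phase.
#'
#' @param startCoords coordinates to start from (previous window's snapshot
#'   or the initial state).
#' @param model an [AtomicModel-class] providing masses (coordinates are
#'   taken from `startCoords`).
#' @param potential a [ToyPotential-class].
#' @param groupNames umbrella group tags (in `groups(model)`).
#' @param index window number.
#' @param targetMap optional target [DensityMap-class].
#' @param params protocol parameter list; see [protocolParams()].
#' @param steering optional list of steering restraint objects (ramped off
#'   during equilibration).
#' @param extraRestraints restraints active only in the fitting phase
#'   (flat-bottom, RMSD caps).
#' @return a [WindowRecord-class].
#' @export
runWindow <- function(startCoords, model, potential, groupNames, index = 1L,
                      targetMap = NULL, params = protocolParams(),
                      steering = list(), extraRestraints = list()) {
  massv <- model@masses
  gidx <- lapply(groupNames, function(g) resolveSelection(model, g))
  comOf <- function(coords)
    t(vapply(gidx, function(ii)
      colSums(coords[ii, , drop = FALSE] * massv[ii]) / sum(massv[ii]),
      numeric(3)))
  com0 <- comOf(startCoords)
  wEM <- params$wEM
  cc <- NA_real_
  coords <- startCoords
  if (!is.null(targetMap) && wEM > 0 && params$fitSteps > 0) {
    emPar <- emFitParams(params$resolution, params$nNeighbor, wEM, 1)
    for (try in seq_len(params$maxRetries + 1L)) {
      emPar@wEM <- wEM
      ## an unstable run (non-finite force from an over-strong density
      ## kick) is treated like a cap violation: retry at halved weight
      run <- tryCatch(
        runLangevin(startCoords, massv, potential,
                    restraints = c(steering, extraRestraints),
                    nSteps = params$fitSteps, dt = params$dt,
                    temperature = params$temperature,
                    friction = params$friction,
                    emTerm = list(map = targetMap, params = emPar,
                                  stride = params$emStride,
                                  exclude = params$emExclude),
                    seed = params$seed + 1000L * index + try),
        error = function(e) e)
      bad <- inherits(run, "error")
      shift <- if (bad) Inf else
        max(sqrt(rowSums((comOf(run$coords) - com0)^2)))
      if (shift <= params$cap || try > params$maxRetries) {
        if (shift > params$cap)
          stop(sprintf(
            "runWindow %d: displacement cap %.2f A violated after %d retries (max shift %.2f A%s)",
            index, params$cap, params$maxRetries, shift,
            if (bad) paste0("; last error: ", conditionMessage(run))
            else ""))
        coords <- run$coords
        cc <- run$cc
        break
      }
      wEM <- wEM * 0.5
    }
  } else if (length(steering) || length(extraRestraints)) {
    run <- runLangevin(startCoords, massv, potential,
                       restraints = c(steering, extraRestraints),
                       nSteps = params$fitSteps, dt = params$dt,
                       temperature = params$temperature,
                       friction = params$friction,
                       seed = params$seed + 1000L * index)
    coords <- run$coords
  }
  comShift <- max(sqrt(rowSums((comOf(coords) - com0)^2)))
  centers <- comOf(coords)
  kvec <- rep_len(params$biasK, length(gidx))
  bias <- lapply(seq_along(gidx), function(g)
    comRestraint(gidx[[g]], centers[g, ], kvec[g], params$biasForm))
  eq <- runLangevin(coords, massv, potential,
                    restraints = c(bias, steering),
                    nSteps = params$equilSteps, dt = params$dt,
                    temperature = params$temperature,
                    friction = params$friction,
                    rampDown = if (length(steering))
                      length(bias) + seq_along(steering) else integer(),
                    seed = params$seed + 1000L * index + 500L)
  half1 <- as.integer(round(params$sampleSteps * params$restartFraction))
  s1 <- runLangevin(eq$coords, massv, potential, restraints = bias,
                    nSteps = half1, dt = params$dt,
                    temperature = params$temperature,
                    friction = params$friction, velocities = eq$velocities,
                    groups = gidx, recordEvery = params$sampleEvery,
                    seed = params$seed + 1000L * index + 600L)
  snapshot <- s1$coords
  s2 <- runLangevin(s1$coords, massv, potential, restraints = bias,
                    nSteps = params$sampleSteps - half1, dt = params$dt,
                    temperature = params$temperature,
                    friction = params$friction,
                    velocities = s1$velocities,
                    groups = gidx, recordEvery = params$sampleEvery,
                    seed = params$seed + 1000L * index + 700L)
  series <- abind2(s1$series, s2$series)
  new("WindowRecord", index = as.integer(index), wEM = wEM,
      biasCenters = centers, biasK = kvec, biasForm = params$biasForm,
      series = series, snapshot = snapshot, finalCoords = s2$coords,
      cc = if (is.null(cc)) NA_real_ else cc, comShift = comShift)
}

## bind two (n x g x 3) arrays along dim 1 (either may be NULL)
abind2 <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Default protocol parameters (toy scale)
#'
#' Phase durations are configuration-scaled toy defaults; the reference
#' protocol's nanosecond phases map onto thousands of steps here.
#'
#' @param dt time step, ps.
#' @param temperature Kelvin.
#' @param friction 1/ps.
#' @param fitSteps,equilSteps,sampleSteps steps per phase.
#' @param sampleEvery record stride in the sampling phase.
#' @param wEM starting density-fitting weight.
#' @param wEMBounds weight schedule bounds.
#' @param cap per-window umbrella-coordinate displacement cap, Angstrom.
#' @param maxRetries fitting-phase retries before aborting.
#' @param emStride steps between EM-force recomputations (slow-force tier).
#' @param emExclude atom indices with the EM force zeroed.
#' @param resolution,nNeighbor synthesis parameters for the EM term.
#' @param biasK umbrella force constant, kcal/mol/A^2 (reference value 1.0).
#' @param biasForm "k" for V = k |dR|^2 (reference convention).
#' @param restartFraction fraction into the sampling phase providing the
#'   next window's start configuration.
#' @param seed integer seed; each window derives sub-seeds from it.
#' @return named list of parameters.
#' @export
protocolParams <- function(dt = 0.01, temperature = 300, friction = 5,
                           fitSteps = 400L, equilSteps = 400L,
                           sampleSteps = 1200L, sampleEvery = 5L,
                           wEM = 0.05, wEMBounds = c(1e-4, 1),
                           cap = 0.60, maxRetries = 3L, emStride = 4L,
                           emExclude = integer(), resolution = 8,
                           nNeighbor = 4L, biasK = 1.0, biasForm = "k",
                           restartFraction = 0.5, seed = 1L) {
  as.list(environment())
}

#' Run a multi-window EM-fitting / umbrella-sampling protocol
#'
#' Repeats [runWindow()] with the fitting weight adapted between windows by
#' [adaptWEM()].
#'
#' @param model starting [AtomicModel-class] with tagged umbrella groups.
#' @param potential a [ToyPotential-class].
#' @param groupNames umbrella group tags.
#' @param nWindows number of windows.
#' @param targetMap target [DensityMap-class] (or NULL for unbiased
#'   umbrella windows).
#' @param params protocol parameters (see [protocolParams()]).
#' @param steeringFactory optional function(windowIndex, coords) returning a
#'   list of steering restraints for that window.
#' @param steering optional adaptive steering controller:
#'   list(state = [SteeringState-class], groupNames = group tags of the
#'   steered groups, in the state's row order). Each window applies
#'   harmonic steering potentials (V = k/2 |r - r*|^2, k converted from
#'   pN/A) centered at [desiredPosition()]; after the window the
#'   controller is updated with the sampled window-mean positions
#'   (force-constant adaptation and way-point advancement).
#' @return list(windows = list of [WindowRecord-class], wEMTrace, ccTrace,
#'   steeringState = final controller state when steering was used,
#'   steeringTrace = per-window data.frame of k and mean positions).
#' @export
runProtocol <- function(model, potential, groupNames, nWindows,
                        targetMap = NULL, params = protocolParams(),
                        steeringFactory = NULL, steering = NULL) {
  coords <- coords(model)
  wEM <- params$wEM
  records <- vector("list", nWindows)
  wTrace <- numeric(nWindows)
  ccTrace <- numeric(nWindows)
  massv <- model@masses
  stIdx <- NULL
  stTrace <- list()
  if (!is.null(steering)) {
    stIdx <- lapply(steering$groupNames,
                    function(g) resolveSelection(model, g))
    ## match steered groups to umbrella-group columns of the recorded
    ## series so the controller sees sampled means
    ugIdx <- lapply(groupNames, function(g) resolveSelection(model, g))
    stCol <- vapply(stIdx, function(ii) {
      hit <- which(vapply(ugIdx, function(jj) setequal(ii, jj), logical(1)))
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
  }
  for (w in seq_len(nWindows)) {
    params$wEM <- wEM
    steerRes <- list()
    if (!is.null(steeringFactory))
      steerRes <- steeringFactory(w, coords)
    if (!is.null(steering)) {
      centers <- desiredPosition(steering$state)
      kk <- convertForceConstant(steering$state@k)
      steerRes <- c(steerRes, lapply(seq_along(stIdx), function(g)
        comRestraint(stIdx[[g]], centers[g, ], kk[g], form = "k/2")))
    }
    rec <- runWindow(coords, model, potential, groupNames, index = w,
                     targetMap = targetMap, params = params,
                     steering = steerRes)
    records[[w]] <- rec
    wTrace[w] <- rec@wEM
    ccTrace[w] <- rec@cc
    if (!is.null(steering)) {
      means <- t(vapply(seq_along(stIdx), function(g) {
        if (!is.na(stCol[g])) {
          nRec <- dim(rec@series)[1]
          colMeans(rec@series[(nRec %/% 2 + 1L):nRec, stCol[g], ,
                              drop = FALSE][, 1, , drop = FALSE][, 1, ])
        } else {
          ii <- stIdx[[g]]
          colSums(rec@finalCoords[ii, , drop = FALSE] * massv[ii]) /
            sum(massv[ii])
        }
      }, numeric(3)))
      stTrace[[w]] <- data.frame(window = w,
                                 group = seq_along(stIdx),
                                 k_pN = steering$state@k,
                                 stage = steering$state@stage,
                                 x = means[, 1], y = means[, 2],
                                 z = means[, 3])
      steering$state <- updateSteering(steering$state, means)
    }
    wEM <- adaptWEM(rec@comShift, rec@wEM, params$cap, params$wEMBounds)
    coords <- rec@snapshot
  }
  list(windows = records, wEMTrace = wTrace, ccTrace = ccTrace,
       steeringState = if (!is.null(steering)) steering$state,
       steeringTrace = if (length(stTrace)) do.call(rbind, stTrace))
}

#' Convert protocol window records into an UmbrellaDataset
#'
#' @param records list of [WindowRecord-class] objects.
#' @param temperature Kelvin.
#' @return an [UmbrellaDataset-class].
#' @export
windowsToDataset <- function(records, temperature = 300) {
  wins <- lapply(records, function(r)
    list(samples = r@series, centers = r@biasCenters, k = r@biasK,
         form = r@biasForm))
  new("UmbrellaDataset", windows = wins, temperature = temperature)
}
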