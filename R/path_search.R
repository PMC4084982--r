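#' @include AllClasses.R AllGenerics.R sampling_engine.R
NULL

#' Convert a force constant from pN/A to kcal/mol/A^2
#'
#' Computed from physical constants: 1 pN * 1 A = 1e-22 J, times Avogadro's
#' number and divided by 4184 J/kcal gives 1.439e-2 kcal/mol per Angstrom.
#'
#' @param value force constant in pN/A (>= 0).
#' @return force constant in kcal/mol/A^2.
#' @export
convertForceConstant <- function(value) {
  stopifnot(all(value >= 0))
  avogadro <- 6.02214076e23
  jPerKcal <- 4184
  value * (1e-12 * 1e-10 * avogadro / jPerKcal)
}

#' Construct a steering controller state
#'
#' @param start matrix (nSteered x 3) of starting group positions.
#' @param targets list of way-point target matrices (nSteered x 3), visited
#'   in order; the last is the final target.
#' @param delta per-group step length, Angstrom, within [0.3, 0.6].
#' @param k initial force constants, pN/A (reference value 100).
#' @param switchRadius way-point switch radius, Angstrom.
#' @return a [SteeringState-class].
#' @export
steeringState <- function(start, targets, delta = 0.5, k = 100,
                          switchRadius = 2) {
  start <- as.matrix(start)
  if (!is.list(targets)) targets <- list(as.matrix(targets))
  n <- nrow(start)
  new("SteeringState", meanPrev = start,
      targets = lapply(targets, as.matrix), stage = 1L,
      delta = rep_len(delta, n), k = rep_len(as.numeric(k), n),
      switchRadius = switchRadius)
}

#' Desired steering positions for the next window
#'
#' Each steered group's harmonic center is placed a step `delta` beyond its
#' previous-window mean position, along the unit vector toward the current
#' way-point target; when the remaining distance is below `delta` the
#' center clamps to the target (the naive step would overshoot).
#'
#' @param state a [SteeringState-class].
#' @return matrix (nSteered x 3) of harmonic centers, Angstrom.
#' @export
desiredPosition <- function(state) {
  tgt <- state@targets[[state@stage]]
  out <- state@meanPrev
  for (i in seq_len(nrow(out))) {
    v <- tgt[i, ] - state@meanPrev[i, ]
    d <- sqrt(sum(v * v))
    if (d <= state@delta[i] || d == 0) out[i, ] <- tgt[i, ]
    else out[i, ] <- state@meanPrev[i, ] + state@delta[i] * v / d
  }
  out
}

#' Progress of a steered coordinate along its target direction
#'
#' The projection of the realized window-to-window displacement onto the
#' unit vector from the previous mean toward the target: the magnitude of
#' the movement in the steered direction.
#'
#' @param meanN mean position in the current window (3-vector).
#' @param meanPrev mean position in the previous window.
#' @param target the target position.
#' @return scalar projection, Angstrom.
#' @export
progressProjection <- function(meanN, meanPrev, target) {
  u <- target - meanPrev
  nu <- sqrt(sum(u * u))
  if (nu == 0) stop("progressProjection: target equals previous mean")
  sum((meanN - meanPrev) * (u / nu))
}

#' Adapt a steering force constant from realized progress
#'
#' The constant is increased by 25 pN/A when the realized projection fell
#' short of the threshold Delta (movement needs facilitating) and decreased
#' by 25 pN/A otherwise (the potential was stronger than needed), floored
#' at zero.
#'
#' @param k current force constant, pN/A.
#' @param projection realized progress, Angstrom.
#' @param threshold Delta, Angstrom (delta/2 in the reference protocol).
#' @param step adaptation step, pN/A (default 25).
#' @return adapted force constant, pN/A.
#' @export
adaptForceConstant <- function(k, projection, threshold, step = 25) {
  stopifnot(k >= 0)
  max(if (projection < threshold) k + step else k - step, 0)
}

#' Advance the steering controller to the next way-point when reached
#'
#' When every steered group lies within `switchRadius` of its current
#' way-point, the targets switch to the next way-point in the list;
#' otherwise the state is unchanged (way-points are never skipped).
#'
#' @param state a [SteeringState-class].
#' @param currentMeans matrix (nSteered x 3) of current-window means.
#' @return the (possibly advanced) [SteeringState-class].
#' @export
advanceStage <- function(state, currentMeans) {
  if (state@stage >= length(state@targets)) return(state)
  tgt <- state@targets[[state@stage]]
  d <- sqrt(rowSums((as.matrix(currentMeans) - tgt)^2))
  if (all(d <= state@switchRadius))
    state@stage <- state@stage + 1L
  state
}

#' One controller update after a window
#'
#' Applies the progress measurement, force-constant adaptation and
#' way-point advancement in one step, returning the updated state.
#'
#' @param state a [SteeringState-class].
#' @param currentMeans matrix (nSteered x 3) of current-window mean
#'   positions.
#' @return updated [SteeringState-class].
#' @export
updateSteering <- function(state, currentMeans) {
  currentMeans <- as.matrix(currentMeans)
  tgt <- state@targets[[state@stage]]
  for (i in seq_len(nrow(currentMeans))) {
    if (sqrt(sum((tgt[i, ] - state@meanPrev[i, ])^2)) > 0) {
      pr <- progressProjection(currentMeans[i, ], state@meanPrev[i, ],
                               tgt[i, ])
      state@k[i] <- adaptForceConstant(state@k[i], pr, state@delta[i] / 2)
    }
  }
  state@meanPrev <- currentMeans
  advanceStage(state, currentMeans)
}

#' Closed-loop steered crossing of a toy landscape
#'
#' Drives steered groups toward their targets with the adaptive controller:
#' each window runs Langevin dynamics under per-group harmonic steering
#' potentials (V = k/2 |r - r*|^2, k in pN/A) centered at
#' [desiredPosition()], measures the window-mean positions, adapts the
#' force constants by +/- 25 pN/A against the Delta = delta/2 threshold,
#' and advances way-point stages. Stops when all groups are within
#' `tolerance` of the final target or after `maxWindows`.
#'
#' @param coords starting coordinates (n x 3).
#' @param massv masses, amu.
#' @param potential a [ToyPotential-class].
#' @param groups list of atom-index vectors (steered groups).
#' @param state a [SteeringState-class] (targets in order).
#' @param windowSteps Langevin steps per window.
#' @param sampleFraction final fraction of each window used for the mean.
#' @param dt,temperature,friction integrator settings.
#' @param maxWindows window budget.
#' @param tolerance convergence distance to the final target, Angstrom.
#' @param seed integer seed.
#' @return list(coords, state, nWindows, trace = data.frame(window, group,
#'   k_pN, projection, distance), reached).
#' @export
steerToTarget <- function(coords, massv, potential, groups, state,
                          windowSteps = 1500L, sampleFraction = 0.4,
                          dt = 0.01, temperature = 300, friction = 5,
                          maxWindows = 100L, tolerance = 0.5, seed = 1L) {
  finalTgt <- state@targets[[length(state@targets)]]
  gm <- lapply(groups, function(g) massv[g] / sum(massv[g]))
  comOf <- function(xy)
    t(vapply(seq_along(groups), function(g)
      colSums(xy[groups[[g]], , drop = FALSE] * gm[[g]]), numeric(3)))
  trace <- list()
  vel <- NULL
  reached <- FALSE
  w <- 0L
  recEvery <- max(1L, windowSteps %/% 50L)
  while (w < maxWindows) {
    w <- w + 1L
    centers <- desiredPosition(state)
    kk <- convertForceConstant(state@k)
    steer <- lapply(seq_along(groups), function(g)
      comRestraint(groups[[g]], centers[g, ], kk[g], form = "k/2"))
    run <- runLangevin(coords, massv, potential, restraints = steer,
                       nSteps = windowSteps, dt = dt,
                       temperature = temperature, friction = friction,
                       velocities = vel, groups = groups,
                       recordEvery = recEvery,
                       seed = seed + 7L * w)
    coords <- run$coords
    vel <- run$velocities
    nRec <- dim(run$series)[1]
    useFrom <- max(1L, as.integer(ceiling(nRec * (1 - sampleFraction))))
    means <- t(vapply(seq_along(groups), function(g)
      colMeans(run$series[useFrom:nRec, g, , drop = FALSE][, 1, ]),
      numeric(3)))
    tgtNow <- state@targets[[state@stage]]
    for (g in seq_along(groups)) {
      pr <- if (sqrt(sum((tgtNow[g, ] - state@meanPrev[g, ])^2)) > 0)
        progressProjection(means[g, ], state@meanPrev[g, ], tgtNow[g, ])
      else 0
      trace[[length(trace) + 1L]] <- data.frame(
        window = w, group = g, k_pN = state@k[g], projection = pr,
        distance = sqrt(sum((means[g, ] - finalTgt[g, ])^2)),
        stage = state@stage)
    }
    state <- updateSteering(state, means)
    dFinal <- sqrt(rowSums((means - finalTgt)^2))
    if (state@stage == length(state@targets) && all(dFinal <= tolerance)) {
      reached <- TRUE
      break
    }
  }
  list(coords = coords, state = state, nWindows = w,
       trace = do.call(rbind, trace), reached = reached)
}
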