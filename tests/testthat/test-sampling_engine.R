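test_that("toy potential forces match the numerical gradient", {
  pot <- toyPotential(
    bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L), k = c(5, 3),
                       r0 = c(1.5, 2)),
    repulsion = data.frame(i = 1L, j = 3L, eps = 0.5, sigma = 2.5),
    fields = list(list(atoms = 2L, fun = function(xy)
      list(energy = sum(0.7 * xy^2), forces = -1.4 * xy))))
  set.seed(4)
  x <- matrix(rnorm(9, sd = 2), 3, 3)
  ef <- potentialEnergyForce(pot, x)
  h <- 1e-6
  for (i in 1:3) for (a in 1:3) {
    xp <- x; xp[i, a] <- xp[i, a] + h
    xm <- x; xm[i, a] <- xm[i, a] - h
    num <- -(potentialEnergyForce(pot, xp)$energy -
               potentialEnergyForce(pot, xm)$energy) / (2 * h)
    expect_equal(ef$forces[i, a], num, tolerance = 1e-5)
  }
})

test_that("restraint forces match gradients and vanish in dead zones", {
  set.seed(5)
  x <- matrix(rnorm(12, sd = 2), 4, 3)
  massv <- c(12, 1, 16, 14)
  rs <- list(
    comRestraint(1:3, c(0.5, -1, 0), k = 2, form = "k"),
    comRestraint(2:4, c(0, 0, 1), k = 3, form = "k/2"),
    positionalRestraint(c(1L, 4L), x[c(1, 4), ] + 0.7, k = 1.5),
    flatBottomRestraint(1L, 2L, d0 = sqrt(sum((x[1, ] - x[2, ])^2)) - 0.5,
                        tol = 0.1, k = 4),
    rmsdRestraint(1:4, x + 0.9, limit = 0.5, k = 6))
  h <- 1e-6
  for (r in rs) {
    ef <- restraintEnergyForce(r, x, massv)
    F <- matrix(0, 4, 3)
    F[ef$atoms, ] <- F[ef$atoms, ] + ef$forces
    for (i in 1:4) for (a in 1:3) {
      xp <- x; xp[i, a] <- xp[i, a] + h
      xm <- x; xm[i, a] <- xm[i, a] - h
      num <- -(restraintEnergyForce(r, xp, massv)$energy -
                 restraintEnergyForce(r, xm, massv)$energy) / (2 * h)
      expect_equal(F[i, a], num, tolerance = 1e-4)
    }
  }
  # flat-bottom restraint: identically zero inside |d - d0| <= 0.1
  d0 <- sqrt(sum((x[1, ] - x[2, ])^2)) + 0.05
  fb <- flatBottomRestraint(1L, 2L, d0 = d0, tol = 0.1, k = 10)
  ef <- restraintEnergyForce(fb, x, massv)
  expect_identical(ef$energy, 0)
  expect_true(all(ef$forces == 0))
  # RMSD cap: zero at RMSD below the limit
  rc <- rmsdRestraint(1:4, x + 0.1, limit = 1, k = 10)
  ef <- restraintEnergyForce(rc, x, massv)
  expect_identical(ef$energy, 0)
  expect_true(all(ef$forces == 0))
})

test_that("frictionless integration conserves energy on a harmonic dimer", {
  pot <- toyPotential(bonds = data.frame(i = 1L, j = 2L, k = 10, r0 = 1.5))
  xy <- rbind(c(0, 0, 0), c(1.9, 0, 0))
  run <- runLangevin(xy, c(12, 12), pot, list(), nSteps = 10000,
                     dt = 0.0005, temperature = 0, friction = 0,
                     velocities = matrix(0, 2, 3), recordEvery = 10)
  etot <- run$energy + run$kinetic
  # bounded symplectic oscillation, no secular drift
  expect_lt((max(etot) - min(etot)) / max(abs(etot)), 1e-4)
  n <- length(etot)
  drift <- abs(mean(etot[(0.9 * n):n]) - mean(etot[1:(0.1 * n)])) /
    max(abs(etot))
  expect_lt(drift, 1e-5)
})

test_that("a thermostatted bead in a COM restraint satisfies equipartition", {
  # V = k |dr|^2 with k = 2 kcal/mol/A^2: per-axis position variance
  # k_B T / (2 k) at 300 K
  pot <- toyPotential()
  res <- list(comRestraint(1L, c(0, 0, 0), k = 2, form = "k"))
  run <- runLangevin(matrix(0, 1, 3), 12, pot, res, nSteps = 60000,
                     dt = 0.01, temperature = 300, friction = 5,
                     groups = list(1L), recordEvery = 5, seed = 11)
  v <- apply(run$series[, 1, ], 2, var)
  expected <- kBoltzmann * 300 / (2 * 2)
  expect_equal(mean(v), expected, tolerance = 0.05)
})

test_that("trajectories are reproducible under a fixed seed", {
  pot <- toyPotential(bonds = data.frame(i = 1L, j = 2L, k = 4, r0 = 2))
  xy <- rbind(c(0, 0, 0), c(2.2, 0, 0))
  r1 <- runLangevin(xy, c(12, 14), pot, list(), nSteps = 500, dt = 0.01,
                    temperature = 300, friction = 5, seed = 99)
  r2 <- runLangevin(xy, c(12, 14), pot, list(), nSteps = 500, dt = 0.01,
                    temperature = 300, friction = 5, seed = 99)
  expect_identical(r1$coords, r2$coords)
  expect_identical(r1$velocities, r2$velocities)
})

test_that("steepest descent reaches the quadratic minimum monotonically", {
  pot <- toyPotential(bonds = data.frame(i = 1L, j = 2L, k = 10, r0 = 1.5))
  xy <- rbind(c(0, 0, 0), c(2.6, 0, 0))
  mn <- minimizeEnergy(xy, pot, maxSteps = 500, tol = 1e-6)
  expect_true(all(diff(mn$energy) <= 0))
  expect_equal(sqrt(sum((mn$coords[2, ] - mn$coords[1, ])^2)), 1.5,
               tolerance = 1e-4)
  expect_true(mn$converged || length(mn$energy) >= 500)
})

test_that("the fitting-weight controller follows the displacement rule", {
  # shift above the cap: halve
  expect_equal(adaptWEM(0.7, 1e-5, cap = 0.6), 5e-6)
  # small shift: double, clipped at the schedule ceiling
  expect_equal(adaptWEM(0.1, 8e-5, cap = 0.6), 1e-4)
  expect_equal(adaptWEM(0.1, 5e-6, cap = 0.6), 1e-5)
  # in the comfort band: unchanged
  expect_equal(adaptWEM(0.4, 1e-5, cap = 0.6), 1e-5)
  # floor clip
  expect_equal(adaptWEM(2, 1.5e-7, cap = 0.6), 1e-7)
})

test_that("windows sample overlapping distributions and honor the cap", {
  # head-swivel-only assembly, stiff enough that the reference 0.60 A cap
  # binds gently
  fx <- cachedFixture("capProtocol", function() {
    toy <- makeToyRibosome(toyRibosomeSpec(
      ratchetAmplitude = 0, tRNATravel = 0, gateOpening = 0,
      headAmplitude = 8, barrier = 1, kConfine = 1.5))
    maps <- makeStateMaps(toy$endpoints, resolution = 11, spacing = 2)
    ug <- grep("^grp", names(groups(toy$model)), value = TRUE)
    pp <- protocolParams(fitSteps = 300L, equilSteps = 300L,
                         sampleSteps = 600L, sampleEvery = 5L,
                         wEM = 0.05, wEMBounds = c(1e-3, 1), cap = 0.6,
                         emStride = 4L, resolution = 11, seed = 7L)
    res <- runProtocol(toy$model, toy$potential, ug, nWindows = 5,
                       targetMap = maps$INT, params = pp)
    list(toy = toy, res = res)
  })
  res <- fx$res
  shifts <- vapply(res$windows, function(w) w@comShift, numeric(1))
  # per-group COM displacement between consecutive fitting phases stays
  # within the 0.60 A cap
  expect_true(all(shifts <= 0.6))
  # neighbouring windows' sampled COM distributions overlap
  ovl <- function(a, b) {
    br <- seq(min(a, b) - 0.05, max(a, b) + 0.05, by = 0.05)
    pa <- hist(a, br, plot = FALSE)$counts
    pb <- hist(b, br, plot = FALSE)$counts
    sum(pmin(pa / sum(pa), pb / sum(pb)))
  }
  for (w in 1:(length(res$windows) - 1)) {
    s1 <- res$windows[[w]]@series
    s2 <- res$windows[[w + 1]]@series
    ov <- min(vapply(seq_len(dim(s1)[2]), function(g)
      ovl(s1[, g, 2], s2[, g, 2]), numeric(1)))
    expect_gt(ov, 0.05)
  }
  # recorded bias energies are recomputable from the stored series and
  # bias spec (the consistency WHAM relies on)
  w1 <- res$windows[[1]]
  massv <- masses(fx$toy$model)
  gidx <- lapply(grep("^grp", names(groups(fx$toy$model)), value = TRUE),
                 function(g) resolveSelection(fx$toy$model, g))
  comF <- t(vapply(gidx, function(ii)
    colSums(w1@finalCoords[ii, , drop = FALSE] * massv[ii]) / sum(massv[ii]),
    numeric(3)))
  eDirect <- sum(w1@biasK * rowSums((comF - w1@biasCenters)^2))
  eRestraint <- sum(vapply(seq_along(gidx), function(g)
    restraintEnergyForce(
      comRestraint(gidx[[g]], w1@biasCenters[g, ], w1@biasK[g],
                   w1@biasForm),
      w1@finalCoords, massv)$energy, numeric(1)))
  expect_equal(eDirect, eRestraint, tolerance = 1e-10)
})

test_that("without a density force the umbrella centers stay put", {
  toy <- toyFixture()
  ug <- grep("^grp", names(groups(toy$model)), value = TRUE)
  pp <- protocolParams(fitSteps = 200L, equilSteps = 200L,
                       sampleSteps = 400L, sampleEvery = 5L, wEM = 0,
                       seed = 3L)
  res <- runProtocol(toy$model, toy$potential, ug, nWindows = 3,
                     targetMap = NULL, params = pp)
  # centers drift only by thermal noise (well under 1.5 A on this toy)
  c1 <- res$windows[[1]]@biasCenters
  c3 <- res$windows[[3]]@biasCenters
  expect_lt(max(sqrt(rowSums((c3 - c1)^2))), 1.5)
  expect_true(all(is.na(vapply(res$windows, function(w) w@cc, numeric(1)))))
})
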