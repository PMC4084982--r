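test_that("synthesized density integrates to the model mass", {
  # single unit-mass atom placed on a voxel center, effectively untruncated
  m <- atomicModel(matrix(c(0, 0, 0), 1, 3), masses = 1)
  g <- gridSpec(c(-12, -12, -12), 1, 25L)
  mp <- synthesizeMap(m, g, resolution = 5, nNeighbor = 12L)
  expect_equal(sum(mapValues(mp)), 1, tolerance = 1e-6)
  # linearity: two far-apart atoms give the sum of single-atom maps
  m2 <- atomicModel(rbind(c(-6, 0, 0), c(6, 0, 0)), element = c("C", "O"))
  g2 <- gridSpec(c(-16, -10, -10), 1, c(33L, 21L, 21L))
  both <- synthesizeMap(m2, g2, 4, 4)
  a <- synthesizeMap(atomicModel(matrix(c(-6, 0, 0), 1, 3),
                                 element = "C"), g2, 4, 4)
  b <- synthesizeMap(atomicModel(matrix(c(6, 0, 0), 1, 3),
                                 element = "O"), g2, 4, 4)
  expect_equal(mapValues(both), mapValues(a) + mapValues(b),
               tolerance = 1e-12)
  # determinism: bitwise identical on repeat
  expect_identical(mapValues(synthesizeMap(m2, g2, 4, 4)),
                   mapValues(both))
  # atoms outside the margin are an error by default
  gSmall <- gridSpec(c(-3, -3, -3), 1, 7L)
  expect_error(synthesizeMap(m2, gSmall, 4, 4), "outside grid margin")
})

test_that("correlation coefficient has the overlap-form properties", {
  m <- randomModel(10, seed = 2)
  g <- autoGrid(m, 1.5, 6L)
  mp <- synthesizeMap(m, g, 5, 4)
  expect_equal(correlationCoefficient(mp, mp), 1, tolerance = 1e-12)
  # invariant under positive rescaling
  sc <- mp
  sc@values <- sc@values * 7.3
  expect_equal(correlationCoefficient(mp, sc), 1, tolerance = 1e-12)
  # disjoint support gives exactly zero
  far <- transformModel(m, new("RigidTransform", rotation = diag(3),
                               translation = c(60, 0, 0)))
  gBig <- gridSpec(g$origin, g$spacing,
                   g$dims + c(45L, 0L, 0L))
  expect_equal(correlationCoefficient(
    synthesizeMap(m, gBig, 5, 4), synthesizeMap(far, gBig, 5, 4)), 0)
  zero <- mp
  zero@values[] <- 0
  expect_error(correlationCoefficient(mp, zero), "identically zero")
})

test_that("self-map correlation is 1 to at least 4 significant digits", {
  # the nNeighbor = 4 truncation keeps CC of a model against its own
  # synthesized map at 1 to >= 4 significant digits
  for (seed in 1:3) {
    m <- randomModel(15, seed = seed)
    g <- autoGrid(m, 2, 6L)
    mp <- synthesizeMap(m, g, 8, 4)
    cc <- correlationCoefficient(synthesizeMap(m, g, 8, 4), mp)
    expect_gt(cc, 1 - 1e-4)
  }
})

test_that("analytic density forces match the numerical CC gradient", {
  set.seed(21)
  m <- randomModel(6, seed = 31)
  g <- autoGrid(m, 1.5, 7L)
  # keep atoms in general position relative to the grid planes (an atom
  # exactly on a plane makes the truncated stencil jump under the FD step)
  g$origin <- g$origin - 0.37 * g$spacing
  target <- synthesizeMap(
    transformModel(m, new("RigidTransform",
                          rotation = rotationMatrix(c(0, 0, 1), 4),
                          translation = c(0.6, -0.3, 0.2))), g, 5, 4)
  params <- emFitParams(5, 4, wEM = 1, kEM = 1)
  f <- emForce(m, target, params)
  h <- 1e-4
  num <- matrix(0, nAtoms(m), 3)
  for (i in seq_len(nAtoms(m))) for (a in 1:3) {
    xp <- coords(m); xp[i, a] <- xp[i, a] + h
    xm <- coords(m); xm[i, a] <- xm[i, a] - h
    mp <- m; mm <- m
    coords(mp) <- xp; coords(mm) <- xm
    num[i, a] <- (correlationCoefficient(synthesizeMap(mp, g, 5, 4), target) -
                  correlationCoefficient(synthesizeMap(mm, g, 5, 4), target)) /
      (2 * h)
  }
  expect_lt(max(abs(f$forces - num)) / max(abs(num)), 1e-5)
})

test_that("a model at its own map optimum feels (near) zero force and a
           displaced model feels a restoring force", {
  m <- randomModel(8, seed = 5)
  g <- autoGrid(m, 1.5, 7L)
  own <- synthesizeMap(m, g, 5, 4)
  params <- emFitParams(5, 4, wEM = 1, kEM = 1)
  atOpt <- emForce(m, own, params, sim = own)
  expect_equal(atOpt$cc, 1, tolerance = 1e-12)
  scale <- max(abs(emForce(
    transformModel(m, new("RigidTransform", rotation = diag(3),
                          translation = c(1, 0, 0))), own,
    params)$forces))
  expect_lt(max(abs(atOpt$forces)), 1e-6 * scale)
  # +x-displaced model: net mass-weighted force points back along -x
  disp <- transformModel(m, new("RigidTransform", rotation = diag(3),
                                translation = c(1.2, 0, 0)))
  f <- emForce(disp, own, params)
  expect_lt(sum(masses(m) * f$forces[, 1]), 0)
})

test_that("the EM weight scaling matches its defining identity", {
  fe <- matrix(c(2, 0, 0), 4, 3, byrow = TRUE)    # |F| = 2 each
  fs <- matrix(c(0, 4, 0), 4, 3, byrow = TRUE)    # |F| = 4 each
  expect_equal(scaleWeight(fe, fs, 1), 2)
  expect_equal(scaleWeight(fe, fs, 0), 0)
  set.seed(14)
  fe <- matrix(rnorm(30), 10, 3)
  fs <- matrix(rnorm(30, sd = 3), 10, 3)
  w <- 0.37
  k <- scaleWeight(fe, fs, w)
  expect_equal(mean(sqrt(rowSums((k * fe)^2))),
               w * mean(sqrt(rowSums(fs^2))), tolerance = 1e-12)
  expect_error(scaleWeight(matrix(0, 3, 3), fs, 1), "zero")
})

test_that("negative clamping zeroes only the negative part", {
  g <- gridSpec(c(0, 0, 0), 1, c(3L, 3L, 3L))
  v <- array(seq(-1, 1, length.out = 27), dim = c(3, 3, 3))
  mp <- new("DensityMap", origin = g$origin, spacing = g$spacing,
            dims = g$dims, values = v, resolution = 5)
  cl <- clampNegative(mp)
  expect_true(all(mapValues(cl) >= 0))
  expect_equal(sum(mapValues(cl)), sum(v[v > 0]))
  pos <- mp; pos@values <- abs(v)
  expect_equal(mapValues(clampNegative(pos)), abs(v))
  expect_identical(cl@origin, mp@origin)
})

test_that("cloud-in-cell regridding conserves density and shifts exactly", {
  m <- randomModel(5, seed = 6)
  g <- autoGrid(m, 1.5, 6L)
  mp <- synthesizeMap(m, g, 4, 4)
  # identity onto the identical grid reproduces the input
  idem <- cicRegrid(mp, identityTransform(), g)
  expect_equal(mapValues(idem), mapValues(mp), tolerance = 1e-12)
  # arbitrary rigid transform conserves total density
  tr <- new("RigidTransform", rotation = rotationMatrix(c(1, 1, 0), 17),
            translation = c(2, 1, -1))
  big <- gridSpec(g$origin - 12, g$spacing, g$dims + 16L)
  rg <- cicRegrid(mp, tr, big)
  expect_equal(sum(mapValues(rg)), sum(mapValues(mp)), tolerance = 1e-9)
  # translation by exactly one voxel shifts indices by one
  sh <- cicRegrid(mp, new("RigidTransform", rotation = diag(3),
                          translation = c(g$spacing[1], 0, 0)),
                  gridSpec(g$origin, g$spacing, g$dims + c(1L, 0L, 0L)))
  expect_equal(mapValues(sh)[2:(g$dims[1] + 1L), , ], mapValues(mp),
               tolerance = 1e-12)
  # support exceeding the target grid is an error with a clipped-mass report
  expect_error(cicRegrid(mp, new("RigidTransform", rotation = diag(3),
                                 translation = c(200, 0, 0)), g),
               "clipped mass")
})

test_that("MRC2014 files round-trip grid metadata and values", {
  m <- randomModel(7, seed = 8)
  g <- autoGrid(m, 2, 5L)
  mp <- synthesizeMap(m, g, 6, 4)
  p <- tempfile(fileext = ".mrc")
  writeMRC(mp, p)
  rd <- readMRC(p, resolution = 6)
  expect_equal(rd@dims, mp@dims)
  expect_equal(rd@origin, mp@origin, tolerance = 1e-5)
  expect_equal(rd@spacing, mp@spacing, tolerance = 1e-6)
  # float32 storage: values agree to single precision
  expect_equal(mapValues(rd), mapValues(mp), tolerance = 1e-6)
})
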