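test_that("the ratchet angle reports the projected intersubunit rotation", {
  toy <- toyFixture()
  post <- toy$endpoints$POST
  # identical structures: zero angle
  expect_lt(abs(ratchetAngle(post, post, "large", "smallbody")), 1e-5)
  # the PRE endpoint is the small subunit rotated by the spec amplitude
  # about the ratchet axis: recovered within 0.1 degree
  expect_equal(ratchetAngle(toy$endpoints$PRE, post, "large", "smallbody"),
               6, tolerance = 0.1 / 6)
  # a synthetic rotation of +5 degrees about the ratchet axis reports +5
  eR <- centerOfMass(post, "large") - centerOfMass(post, "smallbody")
  eR <- eR / sqrt(sum(eR^2))
  idx <- resolveSelection(post, "smallbody")
  com <- centerOfMass(post, "smallbody")
  rot <- post
  xy <- coords(rot)
  xy[idx, ] <- sweep(sweep(xy[idx, , drop = FALSE], 2, com) %*%
                       t(rotationMatrix(eR, 5)), 2, com, "+")
  coords(rot) <- xy
  expect_equal(ratchetAngle(rot, post, "large", "smallbody"), 5,
               tolerance = 0.1 / 5)
  # rotation about an axis perpendicular to the ratchet axis projects to ~0
  perp <- c(-eR[2], eR[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  rotP <- post
  xy <- coords(rotP)
  xy[idx, ] <- sweep(sweep(xy[idx, , drop = FALSE], 2, com) %*%
                       t(rotationMatrix(perp, 5)), 2, com, "+")
  coords(rotP) <- xy
  expect_lt(abs(ratchetAngle(rotP, post, "large", "smallbody")), 0.5)
  # antisymmetry under swapping model and reference
  a1 <- ratchetAngle(rot, post, "large", "smallbody")
  a2 <- ratchetAngle(post, rot, "large", "smallbody")
  expect_equal(a1, -a2, tolerance = 0.2 / 5)
})

test_that("the head angle measures signed in-plane swivel relative to the
           reference", {
  toy <- toyFixture()
  post <- toy$endpoints$POST
  expect_equal(headAngle(post, post, "head", eTRNA = toy$eTRNA,
                         eRatchet = toy$eRatchet), 0, tolerance = 1e-9)
  # the INT endpoint swivels by the spec amplitude (clockwise positive)
  expect_equal(headAngle(toy$endpoints$INT, post, "head",
                         eTRNA = toy$eTRNA, eRatchet = toy$eRatchet,
                         fitSel = "large"), 8, tolerance = 0.2 / 8)
  # constructed -10 degree in-plane rotation reports -10
  b1 <- toy$eTRNA
  b2 <- toy$eRatchet - sum(toy$eRatchet * b1) * b1
  b2 <- b2 / sqrt(sum(b2^2))
  nrm <- c(b1[2] * b2[3] - b1[3] * b2[2],
           b1[3] * b2[1] - b1[1] * b2[3],
           b1[1] * b2[2] - b1[2] * b2[1])
  idx <- resolveSelection(post, "head")
  com <- centerOfMass(post, "head")
  m10 <- post
  xy <- coords(m10)
  xy[idx, ] <- sweep(sweep(xy[idx, , drop = FALSE], 2, com) %*%
                       t(rotationMatrix(nrm, 10)), 2, com, "+")
  coords(m10) <- xy
  expect_equal(headAngle(m10, post, "head", eTRNA = toy$eTRNA,
                         eRatchet = toy$eRatchet), -10,
               tolerance = 0.2 / 10)
  # out-of-plane rotation (about eTRNA itself) projects to ~0
  oop <- post
  xy <- coords(oop)
  xy[idx, ] <- sweep(sweep(xy[idx, , drop = FALSE], 2, com) %*%
                       t(rotationMatrix(b1, 10)), 2, com, "+")
  coords(oop) <- xy
  # leakage is second order in the head-axis tilt: far below the 10
  # degrees applied
  expect_lt(abs(headAngle(oop, post, "head", eTRNA = toy$eTRNA,
                          eRatchet = toy$eRatchet)), 2)
  # antisymmetric under swapping model and reference
  h1 <- headAngle(m10, post, "head", eTRNA = toy$eTRNA,
                  eRatchet = toy$eRatchet)
  h2 <- headAngle(post, m10, "head", eTRNA = toy$eTRNA,
                  eRatchet = toy$eRatchet)
  expect_equal(h1, -h2, tolerance = 0.02)
})

test_that("the gate width is a COM-COM distance invariant under rigid
           motion", {
  # beads with unit masses: A790 at origin, loop residues at 3 and 5
  m <- atomicModel(rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0)),
                   masses = c(1, 1, 1),
                   groups = list(gate_A790 = 1L, gate_G1338 = 2L,
                                 gate_A1339 = 3L))
  expect_equal(gateWidth(m), 4)
  tr <- new("RigidTransform", rotation = rotationMatrix(c(1, 1, 1), 30),
            translation = c(5, -3, 2))
  expect_equal(gateWidth(transformModel(m, tr)), 4, tolerance = 1e-9)
  # random placements match the brute-force COM distance
  set.seed(41)
  for (i in 1:5) {
    xy <- matrix(rnorm(27, sd = 4), 9, 3)
    w <- runif(9, 1, 20)
    mr <- atomicModel(xy, masses = w,
                      groups = list(gate_A790 = 1:3, gate_G1338 = 4:6,
                                    gate_A1339 = 7:9))
    c1 <- colSums(xy[1:3, ] * w[1:3]) / sum(w[1:3])
    c2 <- colSums(xy[4:9, ] * w[4:9]) / sum(w[4:9])
    expect_equal(gateWidth(mr), sqrt(sum((c1 - c2)^2)), tolerance = 1e-12)
  }
  expect_error(gateWidth(m, bodyRes = "gate_MISSING"), "body residue")
})

test_that("screw decomposition inverts screw application", {
  set.seed(42)
  ref <- matrix(rnorm(60, sd = 4), 20, 3)
  # pure rotation about z through the origin
  zscrew <- new("ScrewMotion",
                point = c(0, 0, 0) +
                  sum(colMeans(ref) * c(0, 0, 1)) * c(0, 0, 1),
                direction = c(0, 0, 1), angle = 30, translation = 0)
  dec <- screwDecompose(ref, screwApply(zscrew, ref))
  expect_equal(dec$screw@angle, 30, tolerance = 1e-9)
  expect_equal(dec$screw@translation, 0, tolerance = 1e-9)
  expect_equal(abs(sum(dec$screw@direction * c(0, 0, 1))), 1,
               tolerance = 1e-9)
  # pure translation: degenerate branch with angle 0
  disp <- sweep(ref, 2, c(0, 0, 4), "+")
  decT <- screwDecompose(ref, disp)
  expect_equal(decT$screw@angle, 0)
  expect_equal(decT$screw@translation, 4, tolerance = 1e-9)
  expect_equal(decT$screw@direction, c(0, 0, 1), tolerance = 1e-9)
  # random screws recover all parameters (canonical axis point)
  for (i in 1:25) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0.5, 179)
    tr <- runif(1, -5, 5)
    pt <- rnorm(3, sd = 3)
    pt <- pt + sum((colMeans(ref) - pt) * ax) * ax  # canonical point
    scr <- new("ScrewMotion", point = pt, direction = ax, angle = ang,
               translation = tr)
    dec <- screwDecompose(ref, screwApply(scr, ref))
    sgn <- sign(sum(dec$screw@direction * ax))
    expect_equal(dec$screw@angle, ang, tolerance = 1e-6)
    expect_equal(sgn * dec$screw@translation, tr, tolerance = 1e-6)
    expect_equal(sgn * dec$screw@direction, ax, tolerance = 1e-6)
    expect_equal(dec$screw@point, pt, tolerance = 1e-5)
    expect_lt(dec$residual, 1e-9)
  }
})

test_that("internal/external split is exact and identifies rigid versus
           deformed displacements", {
  m <- toyFixture()$model
  # B = rigidly moved copy of A: internal ~ 0, external = total
  tr <- new("RigidTransform", rotation = rotationMatrix(c(0, 1, 0), 12),
            translation = c(2, 1, -1))
  B <- transformModel(m, tr)
  sp <- splitInternalExternal(m, B)
  expect_lt(max(abs(sp$internal)), 1e-8)
  expect_equal(sp$external, sp$total, tolerance = 1e-8)
  # vector identity internal + external = total holds per atom always
  set.seed(43)
  Bdef <- m
  coords(Bdef) <- coords(m) + matrix(rnorm(3 * nAtoms(m), sd = 0.4),
                                     nAtoms(m), 3)
  sp2 <- splitInternalExternal(m, Bdef, subSels = list(
    head = "head", whole = NULL))
  expect_equal(sp2$internal + sp2$external, sp2$total, tolerance = 1e-12)
  expect_equal(nrow(sp2$magnitudes), 2L)
  # deformation constructed orthogonal to the rigid modes: external ~ 0
  x <- coords(m)
  xc <- sweep(x, 2, colSums(x * masses(m)) / sum(masses(m)))
  d <- xc * 0.02          # pure mass-centered radial breathing
  Bbr <- m
  coords(Bbr) <- x + d
  sp3 <- splitInternalExternal(m, Bbr)
  expect_lt(mean(sqrt(rowSums(sp3$external^2))),
            0.05 * mean(sqrt(rowSums(sp3$total^2))))
})
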