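# UmbrellaDataset with one window, zero bias, samples given as n x 1 x 3
unbiasedDataset <- function(x, temperature = 300) {
  s <- array(0, c(length(x), 1L, 3L))
  s[, 1, 1] <- x
  new("UmbrellaDataset",
      windows = list(list(samples = s, centers = matrix(0, 1, 3), k = 0,
                          form = "k")),
      temperature = temperature)
}

test_that("the unbiased single-window limit gives uniform weights", {
  set.seed(30)
  ds <- unbiasedDataset(rnorm(500))
  sol <- whamSolve(ds)
  expect_equal(sol@F, 0)
  expect_equal(exp(sol@logWeights), rep(1 / 500, 500), tolerance = 1e-12)
  # weights reproduce the empirical histogram exactly
  x <- pooledSamples(ds)[, 1, 1]
  pr <- profile1d(sol, x, breaks = 0.5)
  emp <- hist(x, breaks = seq(floor(min(x) / 0.5) * 0.5,
                              ceiling(max(x) / 0.5) * 0.5 + 0.25,
                              by = 0.5), plot = FALSE)$counts
  expect_equal(pr$weight * 500, emp, tolerance = 1e-9)
})

test_that("WHAM recovers a harmonic free energy from biased windows", {
  L <- makeReferenceLandscape("harmonic", c(k = 1), 300)
  ds <- generateUmbrellaDataset(L, centers = seq(-2, 2, by = 1), biasK = 2,
                                nPerWindow = 3000, seed = 3)
  sol <- whamSolve(ds, tol = 1e-4)
  expect_lt(sol@convergence$maxDeltaF, 1e-4)
  x <- pooledSamples(ds)[, 1, 1]
  pr <- profile1d(sol, x, breaks = 0.2)
  qr <- quantile(x, c(0.05, 0.95))
  sel <- pr$x >= qr[1] & pr$x <= qr[2] & !is.na(pr$F)
  dev <- pr$F[sel] - pr$x[sel]^2
  dev <- dev - mean(dev)   # profiles are defined up to a constant
  expect_lt(max(abs(dev)), 0.1)
})

test_that("the solution is invariant to duplication and window order", {
  L <- makeReferenceLandscape("harmonic", c(k = 1), 300)
  ds <- generateUmbrellaDataset(L, centers = c(-1, 0, 1), biasK = 2,
                                nPerWindow = 400, seed = 5)
  sol <- whamSolve(ds)
  # duplicating every sample in every window leaves F_j unchanged
  dup <- ds
  dup@windows <- lapply(ds@windows, function(w) {
    n <- dim(w$samples)[1]
    s2 <- array(0, c(2L * n, dim(w$samples)[2], 3L))
    s2[1:n, , ] <- w$samples
    s2[n + 1:n, , ] <- w$samples
    w$samples <- s2
    w
  })
  solDup <- whamSolve(dup)
  expect_equal(solDup@F, sol@F, tolerance = 1e-6)
  # relabeling windows permutes F_j up to the anchoring constant
  perm <- c(2L, 3L, 1L)
  shuf <- ds
  shuf@windows <- ds@windows[perm]
  solShuf <- whamSolve(shuf)
  Fs <- solShuf@F - solShuf@F[which(perm == 1L)]
  # agreement bounded by the self-consistency tolerance
  expect_lt(max(abs(Fs[order(perm)] - (sol@F - sol@F[1]))), 5e-4)
})

test_that("non-overlapping windows raise a warning", {
  L <- makeReferenceLandscape("harmonic", c(k = 0.05), 300)
  ds <- generateUmbrellaDataset(L, centers = c(-30, 30), biasK = 50,
                                nPerWindow = 200, seed = 6,
                                proposalSd = 0.2)
  expect_warning(try(whamSolve(ds, maxIter = 2000L), silent = TRUE),
                 "overlap")
})

test_that("R1 projects the masked displacement onto the transition
           direction after superposition", {
  set.seed(31)
  g <- 6
  Ri <- matrix(rnorm(3 * g, sd = 5), g, 3)
  dir <- matrix(rnorm(3 * g), g, 3)
  Rf <- Ri + dir
  mask <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)  # exclude one group
  # linear identities hold exactly in a fixed frame (no superposition)
  fr <- projectionFrame(Ri, Rf, mask = mask, superpose = FALSE)
  len <- sqrt(sum(dir[mask, ]^2))
  expect_equal(projectR1(Ri, fr), 0, tolerance = 1e-9)
  expect_equal(projectR1(Rf, fr), len, tolerance = 1e-9)
  expect_equal(projectR1((Ri + Rf) / 2, fr), len / 2, tolerance = 1e-9)
  # the excluded group does not contribute
  RiX <- Ri
  RiX[6, ] <- RiX[6, ] + c(100, 0, 0)
  expect_equal(projectR1(RiX, fr), 0, tolerance = 1e-6)
  # with superposition on, a rigidly rotated + translated copy of the
  # reference still projects to zero (global drift is removed)
  frS <- projectionFrame(Ri, Rf, mask = mask, superpose = TRUE)
  R <- rotationMatrix(c(1, 2, 0), 20)
  moved <- sweep(Ri %*% t(R), 2, c(4, -2, 1), "+")
  expect_equal(projectR1(moved, frS), 0, tolerance = 1e-6)
  # degenerate references refuse to project
  expect_error(projectR1(Ri, projectionFrame(Ri, Ri, mask = mask)),
               "zero-length")
})

test_that("R2 is the signed travel coordinate along the P-to-E direction", {
  fr <- projectionFrame(matrix(0, 2, 3), matrix(1, 2, 3),
                        rPI = c(0, 0, 0), rEI = c(2, 0, 0))
  # at the E anchor the coordinate is zero
  expect_equal(projectR2(c(2, 0, 0), fr), 0)
  # +2 A along eTRNA (the P -> E direction) is +2
  expect_equal(projectR2(c(4, 0, 0), fr), 2)
  # toward the P site is negative
  expect_equal(projectR2(c(1, 0, 0), fr), -1)
  # perpendicular displacement: |r - rE| * (e_X . e_tRNA) equals the
  # brute-force evaluation of the anchored construction
  set.seed(32)
  for (i in 1:10) {
    rX <- rnorm(3, sd = 3)
    d <- rX - c(2, 0, 0)
    eX <- d / sqrt(sum(d^2))
    expect_equal(projectR2(rX, fr),
                 sqrt(sum(d^2)) * sum(eX * c(1, 0, 0)), tolerance = 1e-12)
  }
})

test_that("1-D profiles are correctly normalized with gap handling", {
  set.seed(33)
  ds <- unbiasedDataset(runif(4000, -2, 2))
  sol <- whamSolve(ds)
  x <- pooledSamples(ds)[, 1, 1]
  pr <- profile1d(sol, x, breaks = 0.5)
  # flat sampling: flat profile within noise
  inner <- pr$F[pr$x > -1.9 & pr$x < 1.9]
  expect_lt(max(inner) - min(inner), 0.15)
  expect_equal(min(pr$F, na.rm = TRUE), 0)
  # density integrates to one
  expect_equal(sum(pr$density * 0.5), 1, tolerance = 1e-9)
  # harmonic sampling: quadratic profile with the right curvature
  L <- makeReferenceLandscape("harmonic", c(k = 1.5), 300)
  dsh <- generateUmbrellaDataset(L, centers = 0, biasK = 0,
                                 nPerWindow = 20000, seed = 8,
                                 proposalSd = 0.5)
  solh <- whamSolve(dsh)
  xh <- pooledSamples(dsh)[, 1, 1]
  prh <- profile1d(solh, xh, breaks = 0.2)
  sel <- !is.na(prh$F) & abs(prh$x) < 0.8
  fit <- lm(prh$F[sel] ~ I(prh$x[sel]^2))
  expect_equal(unname(coef(fit)[2]), 1.5, tolerance = 0.1)
  # interior empty bins are gaps, not interpolated
  ds2 <- unbiasedDataset(c(runif(200, -2, -1), runif(200, 1, 2)))
  sol2 <- whamSolve(ds2)
  pr2 <- profile1d(sol2, pooledSamples(ds2)[, 1, 1], breaks = 0.5)
  expect_true(any(is.na(pr2$F[pr2$x > -1 & pr2$x < 1])))
})

test_that("weighted averages match brute-force per-bin statistics", {
  set.seed(34)
  x <- runif(2000, -2, 2)
  ds <- unbiasedDataset(x)
  sol <- whamSolve(ds)
  xs <- pooledSamples(ds)[, 1, 1]
  # constant observable: mean = c, rmsd = 0
  wa <- weightedAverage(sol, xs, rep(3.7, 2000), breaks = 0.5)
  expect_equal(wa$mean[!is.na(wa$mean)],
               rep(3.7, sum(!is.na(wa$mean))), tolerance = 1e-9)
  expect_equal(max(wa$rmsd, na.rm = TRUE), 0, tolerance = 1e-6)
  # A = X reproduces bin centers within half a bin width
  wa2 <- weightedAverage(sol, xs, xs, breaks = 0.5)
  ok <- !is.na(wa2$mean)
  expect_true(all(abs(wa2$mean[ok] - wa2$x[ok]) <= 0.25 + 1e-9))
  # random observable matches direct weighted statistics per bin
  a <- rnorm(2000)
  wa3 <- weightedAverage(sol, xs, a, breaks = 1)
  w <- exp(sol@logWeights)
  br <- seq(floor(min(xs)), ceiling(max(xs)) + 0.5, by = 1)
  bin <- findInterval(xs, br, rightmost.closed = TRUE)
  for (bb in unique(bin)) {
    ii <- bin == bb
    expect_equal(wa3$mean[bb], sum(w[ii] * a[ii]) / sum(w[ii]),
                 tolerance = 1e-9)
    m <- sum(w[ii] * a[ii]) / sum(w[ii])
    expect_equal(wa3$rmsd[bb],
                 sqrt(sum(w[ii] * (a[ii] - m)^2) / sum(w[ii])),
                 tolerance = 1e-7)
  }
})

test_that("2-D landscapes marginalize to 1-D profiles and factorize for
           independent coordinates", {
  set.seed(35)
  n <- 6000
  x <- rnorm(n, sd = 1)
  y <- rnorm(n, sd = 0.7)
  s <- array(0, c(n, 1L, 3L))
  s[, 1, 1] <- x
  ds <- new("UmbrellaDataset",
            windows = list(list(samples = s, centers = matrix(0, 1, 3),
                                k = 0, form = "k")),
            temperature = 300)
  sol <- whamSolve(ds)
  brX <- seq(floor(min(x)) - 0.5, ceiling(max(x)) + 0.5, by = 0.5)
  brY <- seq(floor(min(y)) - 0.5, ceiling(max(y)) + 0.5, by = 0.5)
  ls <- landscape2d(sol, x, y, brX, brY)
  # marginalizing the 2-D density over y reproduces the 1-D profile
  pr <- profile1d(sol, x, brX)
  margin <- rowSums(ls$density * 0.5)   # integrate over y bins
  expect_equal(margin, pr$density, tolerance = 1e-10)
  # independence: F(x, y) ~ F(x) + F(y) + const on well-sampled cells
  pry <- profile1d(sol, y, brY)
  Fsum <- outer(pr$F, pry$F, "+")
  ok <- !is.na(ls$F) & ls$density > 0.005
  dev <- (ls$F - Fsum)[ok]
  expect_lt(max(dev) - min(dev), 0.6)
  # 2-D harmonic toy: elliptic contours with the analytic curvatures
  kT <- kBoltzmann * 300
  cx <- lm(as.vector(ls$F)[ok] ~ I(rep(ls$x, length(ls$y))[as.vector(ok)]^2) +
             I(rep(ls$y, each = length(ls$x))[as.vector(ok)]^2))
  expect_equal(unname(coef(cx)[2]), kT / 2, tolerance = 0.1)
  expect_equal(unname(coef(cx)[3]), kT / (2 * 0.49), tolerance = 0.1)
})
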