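#' @include AllClasses.R AllGenerics.R structure_model.R
NULL

## Bias energy of window spec `win` evaluated on sample matrices.
## samples: array (n x g x 3); returns numeric n (kcal/mol).
.biasEnergy <- function(samples, centers, k, form) {
  n <- dim(samples)[1]
  d2 <- matrix(0, n, dim(samples)[2])
  for (g in seq_len(dim(samples)[2])) {
    dg <- sweep(samples[, g, , drop = FALSE][, 1, , drop = TRUE],
                2L, centers[g, ])
    if (is.null(dim(dg))) dg <- matrix(dg, 1L, 3L)
    d2[, g] <- rowSums(dg * dg)
  }
  fac <- if (form == "k") 1 else 0.5
  as.numeric(d2 %*% (fac * k))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Solve the multidimensional WHAM equations
#'
#' Self-consistent estimation of per-window free-energy shifts F_j and
#' per-sample unbiased weights from umbrella-sampled windows. The
#' high-dimensional unbiased histogram is never materialized: the solution
#' is kept in sample-reweighting form (each pooled sample receives an
#' unbiased weight), and any projected histogram or average is a weighted
#' sum over samples — mathematically equivalent to the delta-function
#' projection of the full-dimensional distribution.
#'
#' Iteration stops when max |Delta F_j| between successive iterations falls
#' below `tol` (kcal/mol). F_1 is anchored at zero.
#'
#' @param data an [UmbrellaDataset-class].
#' @param tol convergence tolerance, kcal/mol (default 1e-4).
#' @param maxIter iteration cap.
#' @param overlapWarn warn when the minimum nearest-neighbour pairwise
#'   sampling overlap falls below this value.
#' @return a [WhamSolution-class].
#' @export
whamSolve <- function(data, tol = 1e-4, maxIter = 20000L,
                      overlapWarn = 1e-3) {
  wins <- data@windows
  nw <- length(wins)
  kT <- kBoltzmann * data@temperature
  nj <- vapply(wins, function(w) dim(w$samples)[1], integer(1))
  ## pooled samples: bias energy of every window at every sample
  ## U[t, j] = V_j(R_t) / kT
  Ulist <- lapply(seq_len(nw), function(i) {
    s <- wins[[i]]$samples
    vapply(seq_len(nw), function(j)
      .biasEnergy(s, wins[[j]]$centers, wins[[j]]$k, wins[[j]]$form) / kT,
      numeric(dim(s)[1]))
  })
  U <- do.call(rbind, lapply(Ulist, function(u)
    matrix(u, ncol = nw)))
  winIdx <- rep(seq_len(nw), nj)
  N <- nrow(U)
  if (nw > 1L) {
    ## sampled-bias overlap proxy between consecutive windows: fraction of
    ## window j's samples whose bias energy in window j+1 is < 5 kT
    ov <- vapply(seq_len(nw - 1L), function(j)
      mean(Ulist[[j]][, j + 1L] < 5), numeric(1))
    if (any(ov < overlapWarn))
      warning("whamSolve: neighbouring windows with vanishing overlap: ",
              paste(which(ov < overlapWarn), collapse = ", "))
  }
  f <- numeric(nw)  # f_j = F_j / kT
  logN <- log(nj)
  for (iter in seq_len(maxIter)) {
    ## log denominator per sample: log sum_j n_j exp(f_j - U_tj)
    A <- sweep(-U, 2L, f + logN, "+")
    mA <- apply(A, 1L, max)
    logDen <- mA + log(rowSums(exp(A - mA)))
    logw <- -logDen                     # unnormalized log weights
    ## f_j_new = -log sum_t w_t exp(-U_tj)
    B <- logw - U
    mB <- apply(B, 2L, max)
    fNew <- -(mB + log(colSums(exp(sweep(B, 2L, mB)))))
    fNew <- fNew - fNew[1L]
    dmax <- max(abs(fNew - f)) * kT
    f <- fNew
    if (dmax < tol) break
  }
  if (dmax >= tol)
    stop(sprintf("whamSolve: no convergence after %d iterations (residual %.3g kcal/mol)",
                 maxIter, dmax))
  A <- sweep(-U, 2L, f + logN, "+")
  mA <- apply(A, 1L, max)
  logw <- -(mA + log(rowSums(exp(A - mA))))
  logw <- logw - .logsumexp(logw)
  new("WhamSolution", F = f * kT, logWeights = logw,
      windowIndex = as.integer(winIdx), temperature = data@temperature,
      convergence = list(iterations = iter, maxDeltaF = dmax,
                         tolerance = tol))
}

#' Pool umbrella samples into one array
#'
#' @param data an [UmbrellaDataset-class].
#' @return array (nTotal x nGroups x 3) of pooled samples in window order
#'   (matching the weight order of [whamSolve()]).
#' @export
pooledSamples <- function(data) {
  arrs <- lapply(data@windows, function(w) w$samples)
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  g <- dim(arrs[[1]])[2]
  out <- array(NA_real_, c(n, g, 3L))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Build a projection frame for the R1 / R2 reaction coordinates
#'
#' @param Ri initial umbrella-coordinate reference, matrix (nGroups x 3).
#' @param Rf final (target) reference, matrix (nGroups x 3).
#' @param mask logical over groups: TRUE for groups entering the ratchet
#'   projection (default all; the reference analysis excludes the
#'   factor-side proteins — L10, the four L12s and EF-G).
#' @param rPI,rEI initial P-site and E-site anchor positions (Angstrom)
#'   defining the tRNA travel direction eTRNA = unit(rEI - rPI).
#' @param superpose rigidly superpose each sample's masked coordinates onto
#'   Ri before projecting R1 (unit weight per group).
#' @return a [ProjectionFrame-class].
#' @export
projectionFrame <- function(Ri, Rf, mask = rep(TRUE, nrow(Ri)),
                            rPI = c(0, 0, 0), rEI = c(1, 0, 0),
                            superpose = TRUE) {
  e <- rEI - rPI
  ne <- sqrt(sum(e * e))
  if (ne == 0) stop("projectionFrame: P and E anchors coincide")
  new("ProjectionFrame", mask = mask, Ri = as.matrix(Ri),
      Rf = as.matrix(Rf), eTRNA = e / ne, rEI = as.numeric(rEI),
      rPI = as.numeric(rPI), superpose = superpose)
}

## Rigid superposition (unit weights) of point rows x onto y; returns the
## transformed x.
.superposePoints <- function(x, y) {
  k <- .kabsch(x, y, rep(1, nrow(x)))
  sweep(x %*% t(k$rotation), 2L, k$translation, "+")
}

#' Project samples onto the ratchet-progress coordinate R1
#'
#' R1 is the projection of the masked umbrella-coordinate displacement from
#' its initial reference onto the unit vector toward the final reference:
#' how far the ratchet-like rearrangement has progressed. Each sample's
#' masked coordinates are first rigidly superposed onto the initial
#' reference (removing global drift), then projected.
#'
#' @param samples array (n x nGroups x 3) of umbrella-coordinate samples
#'   (see [pooledSamples()]), or a matrix (nGroups x 3) for one sample.
#' @param frame a [ProjectionFrame-class].
#' @return numeric vector of R1 values, Angstrom.
#' @export
projectR1 <- function(samples, frame) {
  if (is.matrix(samples)) {
    samples <- array(samples, c(1L, dim(samples)))
  }
  mi <- which(frame@mask)
  Ri <- frame@Ri[mi, , drop = FALSE]
  Rf <- frame@Rf[mi, , drop = FALSE]
  u <- Rf - Ri
  nu <- sqrt(sum(u * u))
  if (nu == 0) stop("projectR1: zero-length reference difference")
  u <- u / nu
  n <- dim(samples)[1]
  out <- numeric(n)
  for (t in seq_len(n)) {
    S <- samples[t, mi, , drop = TRUE]
    if (is.null(dim(S))) S <- matrix(S, length(mi), 3L)
    if (frame@superpose) S <- .superposePoints(S, Ri)
    out[t] <- sum((S - Ri) * u)
  }
  out
}

#' Project a group position onto the tRNA-travel coordinate R2
#'
#' The signed distance of a group's center of mass from the initial E-site
#' anchor along the P-to-E travel direction: R2 = |r_X - r_E^i| (e_X .
#' e_tRNA) with e_X the unit vector from the E-site anchor to r_X, which
#' equals the projection (r_X - r_E^i) . e_tRNA. Positive R2 means
#' displacement in the direction of translocation from the P- toward the
#' E-site.
#'
#' @param rX position(s) of the tracked group: a 3-vector or an (n x 3)
#'   matrix.
#' @param frame a [ProjectionFrame-class].
#' @return numeric R2 value(s), Angstrom.
#' @export
projectR2 <- function(rX, frame) {
  if (is.null(dim(rX))) rX <- matrix(rX, 1L, 3L)
  d <- sweep(rX, 2L, frame@rEI)
  r <- sqrt(rowSums(d * d))
  eX <- d / ifelse(r > 0, r, 1)
  as.numeric(r * (eX %*% frame@eTRNA))
}

## Weighted histogram of x with weights w on `breaks`; returns per-bin
## weight sums (length length(breaks)-1).
.whist <- function(x, w, breaks) {
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= length(breaks) - 1L
  out <- numeric(length(breaks) - 1L)
  if (any(ok)) {
    acc <- rowsum(w[ok], bin[ok])
    out[as.integer(rownames(acc))] <- as.numeric(acc)
  }
  out
}

#' One-dimensional free-energy profile from WHAM weights
#'
#' F(X) = -kT log of the weighted histogram of the projected coordinate,
#' shifted so the lowest free energy is zero. Empty bins interior to the
#' sampled range are reported as NA gaps, never interpolated.
#'
#' @param solution a [WhamSolution-class].
#' @param x projected coordinate per pooled sample.
#' @param breaks bin breaks covering the sampled range, or a single bin
#'   width (default 1 Angstrom bins spanning the data).
#' @return data.frame(x = bin centers, F = free energy (kcal/mol, min 0),
#'   density = normalized probability density, weight = bin weight sums).
#' @export
profile1d <- function(solution, x, breaks = 1) {
  w <- exp(solution@logWeights)
  stopifnot(length(x) == length(w))
  if (length(breaks) == 1L)
    breaks <- seq(floor(min(x) / breaks) * breaks,
                  ceiling(max(x) / breaks) * breaks + breaks / 2,
                  by = breaks)
  h <- .whist(x, w, breaks)
  widths <- diff(breaks)
  dens <- h / (sum(h) * widths)
  kT <- kBoltzmann * solution@temperature
  F <- ifelse(h > 0, -kT * log(h), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  data.frame(x = (breaks[-1] + breaks[-length(breaks)]) / 2,
             F = F, density = dens, weight = h)
}

#' Weighted average and spread of an observable along a coordinate
#'
#' Per-bin unbiased-weighted mean of an observable and its weighted
#' root-mean-square deviation about that mean.
#'
#' @param solution a [WhamSolution-class].
#' @param x projected coordinate per pooled sample.
#' @param a observable value per pooled sample.
#' @param breaks bin breaks or single width (as in [profile1d()]).
#' @return data.frame(x = bin centers, mean, rmsd, weight); empty bins NA.
#' @export
weightedAverage <- function(solution, x, a, breaks = 1) {
  w <- exp(solution@logWeights)
  stopifnot(length(x) == length(w), length(a) == length(w))
  if (length(breaks) == 1L)
    breaks <- seq(floor(min(x) / breaks) * breaks,
                  ceiling(max(x) / breaks) * breaks + breaks / 2,
                  by = breaks)
  sw <- .whist(x, w, breaks)
  swa <- .whist(x, w * a, breaks)
  swa2 <- .whist(x, w * a * a, breaks)
  mean <- ifelse(sw > 0, swa / sw, NA_real_)
  var <- ifelse(sw > 0, pmax(swa2 / sw - mean^2, 0), NA_real_)
  data.frame(x = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mean = mean, rmsd = sqrt(var), weight = sw)
}

#' Two-dimensional free-energy landscape from WHAM weights
#'
#' F(X, Y) = -kT log of the 2-D weighted histogram, minimum set to zero.
#'
#' @param solution a [WhamSolution-class].
#' @param x,y projected coordinates per pooled sample.
#' @param breaksX,breaksY bin breaks or single widths.
#' @return list(x, y = bin centers, F = matrix (nx x ny), density =
#'   normalized 2-D density matrix).
#' @export
landscape2d <- function(solution, x, y, breaksX = 1, breaksY = 1) {
  w <- exp(solution@logWeights)
  mk <- function(v, b) {
    if (length(b) == 1L)
      b <- seq(floor(min(v) / b) * b, ceiling(max(v) / b) * b + b / 2,
               by = b)
    b
  }
  breaksX <- mk(x, breaksX)
  breaksY <- mk(y, breaksY)
  bx <- findInterval(x, breaksX, rightmost.closed = TRUE)
  by <- findInterval(y, breaksY, rightmost.closed = TRUE)
  nx <- length(breaksX) - 1L
  ny <- length(breaksY) - 1L
  ok <- bx >= 1L & bx <= nx & by >= 1L & by <= ny
  H <- matrix(0, nx, ny)
  if (any(ok)) {
    lin <- bx[ok] + (by[ok] - 1L) * nx
    acc <- rowsum(w[ok], lin)
    H[as.integer(rownames(acc))] <- as.numeric(acc)
  }
  kT <- kBoltzmann * solution@temperature
  F <- ifelse(H > 0, -kT * log(H), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  cellArea <- outer(diff(breaksX), diff(breaksY))
  list(x = (breaksX[-1] + breaksX[-(nx + 1L)]) / 2,
       y = (breaksY[-1] + breaksY[-(ny + 1L)]) / 2,
       F = F, density = H / (sum(H) * cellArea))
}
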