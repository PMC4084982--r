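# Shared fixtures, built in code. Heavier objects are cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# small random bead model with distinct inertia moments
randomModel <- function(n = 12, seed = 1, spread = c(3, 2, 1.2),
                        element = "C") {
  set.seed(seed)
  atomicModel(matrix(rnorm(3 * n), n, 3) %*% diag(spread),
              element = element)
}

# toy assembly shared by generator/geometry/protocol tests
toyFixture <- function() {
  cachedFixture("toy", function() makeToyRibosome(toyRibosomeSpec()))
}

# single-bead double-well potential along x with harmonic y/z confinement;
# barrier a*b^4 between minima at x = -b and +b
doubleWellPotential <- function(barrier, b = 2, kPerp = 0.5) {
  a <- barrier / b^4
  toyPotential(fields = list(list(atoms = 1L, fun = function(xy) {
    x <- xy[, 1]
    list(energy = sum(a * (x^2 - b^2)^2) +
           kPerp * sum(xy[, 2]^2 + xy[, 3]^2),
         forces = cbind(-4 * a * x * (x^2 - b^2),
                        -2 * kPerp * xy[, 2], -2 * kPerp * xy[, 3]))
  })))
}

# three-atom PDB text written to a temp file
writeToyPDB <- function(path, hetatm = FALSE, twoModels = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  O   ALA A   2       4.000   1.500   2.000  1.00  0.00           O")
  if (hetatm)
    lines <- c(lines,
      "HETATM    4  PB  GDP B   9       0.500   0.100   9.000  1.00  0.00           P")
  if (twoModels)
    lines <- c("MODEL        1", lines, "ENDMDL", "MODEL        2",
               sub("1.000", "9.000", lines[1]), lines[-1], "ENDMDL")
  writeLines(c(lines, "END"), path)
  path
}
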