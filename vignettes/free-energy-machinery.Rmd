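---
title: "Density-guided sampling and free-energy landscapes with emScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-guided sampling and free-energy landscapes with emScape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emScape)
```

# What this package computes

emScape implements the free-energy machinery used to drive a large
molecular assembly from one conformational state into another along a
pathway dictated by cryo-EM density maps, and to measure the free-energy
landscape along that pathway:

1. **Density synthesis and the fitting objective.** A simulated map is
   computed from atomic coordinates by spreading each atomic mass onto the
   grid with a Gaussian kernel. The fitting objective is the negative
   real-space correlation coefficient (CC) between simulated and
   experimental maps; its analytic gradient with respect to atomic
   positions provides per-atom fitting forces.
2. **Rigid map alignment.** Before flexible fitting, experimental maps are
   aligned onto the atomic model: voxels are thresholded to the molecular
   volume, the model is rigid-fitted by matching inertia moments, the pose
   is refined by CC ascent, and the inverse transform is applied to the map
   with cloud-in-cell (CIC) regridding.
3. **The windowed protocol.** Fitting proceeds in windows: a short
   EM-fitting phase deforms the structure toward the target map, umbrella
   centers are set to the current group centers of mass, the system is
   equilibrated and then sampled under the biases. The fitting weight is
   adapted between windows so that no umbrella coordinate moves more than a
   displacement cap per window, which keeps consecutive windows'
   distributions overlapping.
4. **Adaptive steered targeting.** Selected groups (the tRNA analogues)
   can additionally be pulled by harmonic potentials whose centers advance
   a step `delta` toward a way-point per window and whose force constants
   self-tune by +/- 25 pN/A depending on whether the realized progress
   exceeded `delta / 2`.
5. **Multidimensional WHAM.** The biased samples of the full
   umbrella-coordinate vector are combined by the weighted histogram
   analysis method in sample-reweighting form; free-energy profiles along
   projected reaction coordinates (R1, the ratchet-progress projection;
   R2, the signed tRNA-travel coordinate), weighted averages and 2-D
   landscapes follow as weighted histograms.
6. **Geometric descriptors.** Structure pairs are compared by the
   intersubunit ratchet angle, the signed head-rotation angle, the
   P/E-gate width (a COM-COM distance between a body residue and a
   two-residue head loop), and a Chasles screw-axis decomposition with an
   internal/external motion split.

All of this is exercised end-to-end on synthetic bead assemblies with
known landscapes; the all-atom force field, explicit solvent and
production-scale molecular dynamics of the original application are out of
scope and are replaced by a Langevin engine on toy potentials.

# The density model and its conventions

The simulated density at voxel $V_k$ is
$\rho^{sim}(V_k) = \sum_i m_i\, G(|V_k - r_i|)$ with a Gaussian kernel of
width $\sigma = \text{resolution} \times \sqrt{1/2}/\pi$. This constant
makes the Fourier transform of the kernel fall to $1/e$ of its peak at
spatial frequency $1/\text{resolution}$, one concrete reading of
"resolution = half-width of the Fourier-space Gaussian"; it is a single
configurable parameter (`sigmaFactor`), and every consumer — the CC, the
forces, the tests — is self-consistent for any choice. The kernel is
truncated to the `nNeighbor` (3 or 4) nearest grid planes per axis in each
direction; with 4 planes the CC of a model against its own synthesized map
equals 1 to at least four significant digits, which is the accuracy the
truncation is designed to deliver.

The CC is the non-centered overlap form
$\mathrm{CC} = \sum \rho^{exp}\rho^{sim} / \sqrt{\sum (\rho^{exp})^2 \sum
(\rho^{sim})^2}$, the standard choice in correlation-driven flexible
fitting; experimental maps are clamped non-negative first. The force on
atom $i$ is obtained by differentiating CC with respect to the simulated
voxel densities and chaining through the Gaussian spreading weights of the
same truncated stencil, so the analytic forces match finite differences of
the objective to better than $10^{-4}$ relative error (in practice
$\sim 10^{-9}$ away from stencil boundaries; an atom sitting exactly on a
grid plane makes the truncated objective non-smooth, which is why the test
fixtures keep atoms in general position).

The strength of the density force is controlled by a dimensionless weight
`wEM`: the energy weight is chosen so that the mean per-atom magnitude of
the scaled density force equals `wEM` times the mean structural force
magnitude. The windowed protocol adapts `wEM` multiplicatively (double
below half the cap, halve above the cap, clipped to schedule bounds). The
reference schedule bounds are $10^{-7}$ to $10^{-4}$ for a solvated
million-atom assembly; the toy systems here are far softer and smaller, so
the protocol defaults use wider toy-scale bounds, passed explicitly where
the protocol is run.

# Sampling engine

Dynamics are NVT Langevin (BAOAB discretization; velocity Verlet in the
zero-friction limit), with units kcal/mol, Angstrom, amu, ps and
$k_B = 1.987\times 10^{-3}$ kcal/mol/K. The density force is a slow
force: it is recomputed every few steps and held constant in between.
Restraints follow two harmonic conventions, both recorded explicitly:
umbrella restraints on group centers of mass are $V = k|\Delta R|^2$ with
$k$ in kcal/mol/A$^2$ (the protocol's canonical $k = 1$ gives each
restrained COM an RMSF near 0.2 A at 300 K), while steering restraints are
$V = \tfrac{k}{2}|\Delta r|^2$ with $k$ quoted in pN/A so that force =
$k\times$ displacement; the conversion constant
$1\,\mathrm{pN} = 1.439\times10^{-2}$ kcal/mol/A follows from Avogadro's
number. WHAM consumes the functional form recorded with each window, which
is the only correctness requirement.

Flat-bottom distance restraints contribute nothing while the distance is
within 0.1 A of its ideal value; RMSD caps contribute nothing below a 1 A
limit. Both dead zones are verified to give identically zero energy and
force.

# The synthetic study system

`makeToyRibosome()` builds a two-body bead assembly: a large body (the
frame), a small body carrying an elongated head, two mobile tRNA-like
groups between the bodies, and a three-cluster gate analogue (a body
cluster numbered 790 against a head-loop pair numbered 1338/1339). Three
endpoint conformations are constructed: POST-like (the base), INT-like
(head swiveled clockwise by a stated amplitude, default 8 degrees) and
PRE-like (small subunit rotated by a stated ratchet amplitude, default 6
degrees, tRNA groups displaced by a stated travel, default 4 A, gate
opened by a stated width, default 6 A). Each construction parameter is
recovered by the corresponding descriptor within its documented tolerance,
which ties the generator and the analysis module together.

The structural potential has three tiers chosen to emulate, at desk scale,
the features the protocol actually relies on in a condensed-phase
assembly:

* stiff nearest-neighbour bonds inside each umbrella group (2
  kcal/mol/A$^2$) keep groups quasi-rigid;
* soft links between neighbouring groups (0.02 kcal/mol/A$^2$), with rest
  lengths midway between the endpoint geometries so that neither
  conformation is strained, allow the subunits to reorient;
* a confinement field (0.3 kcal/mol/A$^2$) anchors immobile beads at
  their POST positions and confines mobile beads to a harmonic tube
  around their POST-to-PRE displacement line, standing in for the packing
  of the solvated assembly that a sparse bead network cannot supply; along
  the tube each mobile bead carries a double well with minima at both
  endpoint positions.

The per-bead well depths are distributed in proportion to the squared
displacement (equal well curvature for every bead) and sum to a stated
collective barrier, default 6 kcal/mol. At this value both endpoints are
minima of the potential (endpoint energies agree within ~1 kcal/mol, the
midpoint configuration sits several kcal/mol higher), the endpoints are
weakly metastable at 300 K — the umbrella biases hold the sampled states,
exactly the regime umbrella sampling is designed for — and the density
force at the protocol's weights can actually drive the transition.
A much larger barrier makes the endpoints deeply metastable but
undrivable at weights the displacement cap permits; this trade-off is
intrinsic to the method, not to the implementation.

The displacement cap deserves a note. The reference protocol caps each
umbrella coordinate's per-window displacement at 0.60 A, a value matched
to the stiffness of a 2.1-million-atom solvated complex. On the default
toy, basin-to-basin hops of a tRNA group move its COM by ~2 A in a single
fitting phase, so the end-to-end demonstration uses a toy-scaled cap
(1.5-2.5 A) with the same controller; the cap mechanism itself is
exercised at the reference 0.60 A value on a stiffer head-swivel-only
fixture where thermal COM fluctuations are small (confinement 1.5
kcal/mol/A$^2$), and holds in 100% of windows there.

# WHAM choices

The full $n_{biased}\times 3$-dimensional WHAM is solved in
sample-reweighting form: the self-consistent window shifts $F_j$ give each
pooled sample an unbiased weight, and any projected histogram or average
is a weighted sum — mathematically identical to projecting the
full-dimensional distribution with delta functions, without materializing
an unstorable histogram. Iteration stops when $\max_j |\Delta F_j|$ drops
below $10^{-4}$ kcal/mol; $F_1$ is anchored at zero, and solutions are
invariant (to the convergence tolerance) under window relabeling and
sample duplication. Neighbouring windows whose sampled distributions do
not overlap are reported with a warning, since the stitched profile is
then unreliable across the gap. Profiles use 1 A default bins (0.2-0.5 A
in the tests, which resolve toy-scale features), report empty interior
bins as gaps rather than interpolating, and set the lowest free energy to
zero.

Before projecting R1, each sample's masked coordinates are rigidly
superposed onto the initial reference with unit weight per group; the
superposition removes global drift, so the linear identities (initial
maps to 0, final maps to the full displacement norm, midpoint to half)
hold exactly only in a fixed frame — both behaviours are exposed and
tested. R2 is implemented through the anchored construction
$|r_X - r_E^i|\,(e_X\cdot e_{tRNA})$, which is algebraically equal to the
plain projection $(r_X - r_E^i)\cdot e_{tRNA}$; positive values point
along the P-to-E travel direction.

# Geometry conventions

* **Ratchet angle**: the model is best-fit on the large subunit, the
  residual small-subunit rotation is converted to axis-angle form, and
  the reported value is $\theta\,(e_{rot}\cdot e_{ratchet})$ — a signed
  projection, so rotation about an axis perpendicular to the intersubunit
  axis reports ~0. The sign is fixed so a model whose small subunit is
  rotated $+\theta$ about the ratchet axis relative to the reference
  reports $+\theta$.
* **Head angle**: the head's principal axis most parallel to the tRNA
  travel direction is projected onto the plane spanned by the travel and
  ratchet directions; the in-plane angle relative to the reference is
  reported clockwise-positive (a right-handed in-plane rotation counts
  negative). Principal axes are sign-ambiguous, so each axis is oriented
  by a reference direction before use.
* **Screw decomposition**: the best-fit rotation/translation pair is
  converted to Chasles form; the axis point returned is the point on the
  axis closest to the moving selection's centroid (axis points form a
  line, so serialization needs a canonical representative). Rotations
  below 0.1 degree take a pure-translation branch. The inverse identity
  (decompose after apply) holds to $10^{-6}$ for angles in (0.5, 179)
  degrees.
* **Internal/external split**: external motion is the displacement
  produced by the whole-selection rigid fit of state A onto state B;
  internal motion is the residual; the two sum to the total displacement
  exactly, per atom.

# Numerical and degenerate-input policy

Unknown elements fail loudly unless a mass override is supplied — never a
silent zero mass. Collinear selections refuse to superpose; inertia-tensor
degeneracies (within $10^{-9}$ relative) raise warnings and, in the rigid
map fit, fall back to center-of-mass alignment. The inertia-moment fit
enumerates all proper axis-sign assignments (the handedness of the two
eigenbases decides which four of eight are proper) and scores them by CC.
CIC regridding conserves total density exactly up to floating-point
summation; near-integer voxel fractions are snapped so an identity regrid
is bitwise-faithful; by default any transformed density falling outside
the target grid is an error with a clipped-mass report, with an explicit
tolerance available where sub-permille boundary loss is expected (map
alignment). The CC refinement is a deterministic coordinate-wise pattern
search with shrinking steps (1.0 to 0.05 A, 2.0 to 0.1 degrees), which
satisfies the only contract the alignment needs: the CC never decreases.

# Problem sizes

The test-suite and acceptance computations use deliberately small
problems: bead models of 5-175 atoms, grids up to ~50^3 voxels,
umbrella datasets of 5 windows x 5000 Monte-Carlo samples (harmonic
recovery), 19 Langevin windows x 2000 samples (double-well barrier
recovery, barrier measured against the mean of the two equal well minima
to cancel first-order stitching tilt) and a 17-window end-to-end run:
one undriven window at the POST-like state, then 16 windows driven by
the density force with the adaptive steering controller pulling the two
tRNA-like groups toward their PRE positions — the same combination of
density fitting and per-group steered targeting the windowed protocol is
designed around, since the density gradient alone cannot reliably carry
a group across its own bistability barrier. These sizes give the
statistical resolution the assertions need (for instance, the harmonic
profile is recovered within 0.1 kcal/mol and the double-well barrier
within 15%) while a full run of everything remains a desk-scale
computation.

# What passing tests do and do not show

The synthetic assembly reproduces the *structure* of the real analysis
problem — coupled rigid-body reorientation, group travel, a swivelling
head carrying a gate, maps of distinct states at realistic resolution
(8-11 A), biased sampling with recomputable bias energies — with known
ground truth for every quantity. It does not emulate atomic force-field
physics, solvent, ions, the entropy of real side chains, map noise
statistics of real reconstructions, or the microsecond relaxation times
of the real assembly. Passing tests therefore certify the correctness of
the machinery (forces equal gradients, WHAM recovers known landscapes,
descriptors invert their constructions), not the biological conclusions
one would draw from applying it to experimental data.

# Known limitations

* The Langevin engine is serial, pure R: production-scale systems are out
  of reach by design.
* WHAM error bars (bootstrap/MBAR-style) are not provided.
* The map aligner performs a local search seeded by the inertia-moment
  fit; for maps whose thresholded density cloud is grossly mismatched to
  the model's shape (or near-centrosymmetric), the flip-scored candidates
  may all start in the wrong basin. Global 6-D or FFT-accelerated search
  is out of scope.
* Cross-species structure comparison requires a precomputed atom
  correspondence; no sequence alignment is performed.
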