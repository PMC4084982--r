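Package: emScape
Title: Cryo-EM Guided Flexible Fitting, Umbrella Sampling and Free-Energy
    Landscapes for Coarse Molecular Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Density-map-guided conformational sampling machinery for
    molecular assemblies: synthesis of simulated cryo-EM density maps from
    atomic coordinates with a mass-weighted Gaussian kernel, the real-space
    correlation-coefficient fitting objective and its analytic per-atom
    forces, rigid map-to-model alignment (volume thresholding, inertia-moment
    fitting, correlation refinement, cloud-in-cell regridding), a Langevin
    sampling engine executing the windowed EM-fitting plus umbrella-sampling
    protocol with an adaptive fitting-weight controller, adaptive steered
    targeting of group centers of mass, multidimensional WHAM with projected
    reaction coordinates (intersubunit ratchet progress and tRNA-travel
    position), and structure-pair descriptors for ribosome-like assemblies
    (ratchet angle, head-rotation angle, P/E-gate width, Chasles screw-axis
    decomposition with an internal/external motion split). Synthetic
    two-body "ratchet" bead assemblies and closed-form reference landscapes
    provide statistically controlled test systems for the whole stack.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'structure_model.R'
    'density_maps.R'
    'geometry_analysis.R'
    'sampling_engine.R'
    'path_search.R'
    'rigid_fit.R'
    'synthetic_data.R'
    'wham_landscape.R'
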