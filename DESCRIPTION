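Package: offtalpha
Title: Subunit and Dynamic-Synapse Models of Off-Transient Alpha Ganglion Cell Spatial Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for the spatial selectivity of
    Off-Transient alpha retinal ganglion cells, which respond more strongly to
    spatially homogeneous stimuli than to structured ones. Implements a hybrid
    linear-nonlinear circuit model in which spatially local, center-surround
    inhibitory subunits modulate excitatory subunits through presynaptic
    inhibition acting on a vesicle-depletion synapse. Includes generators for
    the standard stimulus protocols (flashed and contrast-reversing gratings,
    paired dark pulses, spots, synthetic natural-image-like patches with
    linear-equivalent discs), difference-of-Gaussians receptive-field
    machinery with area-summation fitting, F2 subunit analysis, and the
    summary statistics used to quantify homogeneity preference (nonlinearity
    index, paired-pulse ratio, excitation-inhibition temporal offset).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
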