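Package: bridgeflow
Title: Hemodynamics of Bridging Vein-Sinus Junctions by Lattice Boltzmann Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric steady laminar flow simulation of cerebral bridging
    veins entering the superior sagittal sinus, with wall shear stress (WSS)
    profiling along labelled vessel walls. Provides a moment-matched
    truncated-normal generator for anatomically distributed vein cohorts
    (diameter and entry angle), a planar junction geometry builder with six
    labelled wall segments anchored at the dural entrance, a D2Q9 lattice
    Boltzmann solver (TRT/BGK) for the junction flow, WSS plateau and minimum
    analysis along each wall, and the cohort-sweep analysis that locates the
    demarcation threshold separating thrombosis-prone morphologies and
    tabulates minima by entry-angle group and by anterior/posterior group.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
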