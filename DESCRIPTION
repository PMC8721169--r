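Package: hexnotch
Title: Hybrid Logic-ODE Simulation of Delta-Notch Patterning on Hexagonal
    Cell Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven co-simulation of multicellular tissues that couples
    per-cell ordinary differential equation models through discrete logic
    rules. Ships a six-species Delta-Notch lateral-inhibition model on a
    hexagonal grid: each cell's Delta output is binarized at a quantization
    threshold, neighborhood quorum rules set the ligand input of every cell,
    and the coupled tissue is integrated between threshold-crossing events
    until the pattern reaches equilibrium. Includes hexagonal grid geometry
    with bounded, cylindrical and toroidal boundary conditions, a positional
    Wnt gradient input, pattern metrics, YAML run configurations, bundled
    scenario presets, and CSV/JSON/PNG output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
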