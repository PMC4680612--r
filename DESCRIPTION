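Package: sheltertube
Title: Stigmergic Lattice Simulation and Morphometry of Termite
    Shelter-Tube Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of collective shelter-tube and mat
    construction by subterranean termite workers on a two-dimensional
    lattice. Workers choose build sites by an attraction rule combining
    cement-pheromone positive feedback, an edge preference, distance from
    the nest and a direction memory; collision and crowdedness rules end
    tubes and disperse workers. The package also quantifies the resulting
    binary patterns (area, perimeter split into along-edge and
    away-from-edge components), generates synthetic test patterns and
    group tables, and compares groups with one-way ANOVA, so that
    intercolonial pattern variation can be regenerated by varying only
    the active-worker fraction and the pheromone sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
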