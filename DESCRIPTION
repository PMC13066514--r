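Package: larvanet
Title: Larval Dispersal Networks from Lagrangian Particle Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical larval-dispersal connectivity analysis for island
    archipelagos. Simulates passive coral larvae as Lagrangian particles on
    gridded surface currents with a lunar-gated spawning calendar, converts
    trajectories into site-to-site dispersal-percentage matrices, analyses
    the resulting directed networks (betweenness centrality, generation-capped
    stepping-stone dispersal via Floyd-Warshall shortest paths), and compares
    modelled dispersal against genetic differentiation (F_ST) with Mantel
    permutation tests. Includes synthetic generators (idealized boundary-jet
    current fields, island chains, lunar calendars, F_ST matrices with known
    structure) so the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    geosphere,
    vegan,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
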