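Package: proxscreen
Title: Network-Proximity Screening of Compound Target Sets Against Disease Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes small-molecule compounds for a disease by the average
    closest network distance between their protein targets and a set of
    disease-associated proteins on a human protein-protein interactome,
    standardized against a degree- and size-matched randomization null model.
    Includes assembly and filtering of bipartite compound-target interaction
    tables (drug-likeness and prediction-score thresholds), hypergeometric and
    permutation recovery statistics for predicted interactions, mechanism
    subnetwork extraction between targets and disease proteins,
    overrepresentation analysis with Benjamini-Hochberg correction, and a
    seeded synthetic-scenario generator (scale-free interactome, planted
    disease module, proximal/distal compound cohorts, annotation terms) for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
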