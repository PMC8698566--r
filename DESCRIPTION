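Package: androtime
Title: Temporal Clustering and Network Analysis of Rapid Androgen-Response Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for short time-course proteome ratio data from
    androgen-stimulated prostate cancer cells. Standardizes treated-versus-vehicle
    protein ratio profiles over a 0-60 minute time course, clusters them by fuzzy
    c-means with data-size-dependent fuzzifier estimation and elbow-based cluster
    count selection, labels the five temporal archetypes (signal initiators, early
    stimulators, signal mediators, late stimulators, terminal regulators), and
    integrates the clusters with protein annotations and a protein-protein
    interaction network: compartment and molecular-type over-representation,
    cluster-pair interaction statistics, enumeration of C-to-E-via-D signaling
    cascades on a nine-region compartment grid, a Fisher's-exact molecular concept
    map, and consensus differential-expression marker calling across independent
    expression datasets. Includes a synthetic-data generator that emulates the
    study design (five time points, three replicates, two conditions, planted
    temporal archetypes, annotation bias, interaction-pair excess and marker
    genes) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    cluster
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    withr
Config/testthat/edition: 3
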