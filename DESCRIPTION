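Package: nitroscreen
Title: CNS Drug-Likeness Screening and Brain-Blood Partition Prediction
    for Nitrosourea Analogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens candidate small molecules, in particular analogs of the
    anticancer nitrosourea lomustine, for central-nervous-system drug-likeness.
    Computes the standard molecular descriptors (formula weight, topological
    polar surface area by the Ertl fragment method, hydrogen-bond donor and
    acceptor counts, rotatable bonds, an atom-contribution Log P estimate) from
    SMILES via Open Babel, applies Lipinski's Rule of 5 and two published
    blood-brain-barrier penetration criteria sets, predicts the brain-to-blood
    concentration ratio from the linear Log BB model in polar surface area and
    Log P, and provides the accompanying multivariate statistics layer: summary
    statistics, Pearson correlations, Grubbs' extreme studentized deviate
    outlier test, multiple regression, standardized path coefficients, ANOSIM,
    and single-linkage hierarchical clustering. Includes a deterministic
    synthetic-data generator that enumerates nitrosourea analogs on the fixed
    O=C(NHR)N(N=O)CH2CH2Cl core and simulates descriptor tables with the
    statistical structure of the reference agent set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
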