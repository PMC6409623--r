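Package: PheWASRank
Title: Gene Prioritization by Network Propagation of PheWAS Association Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes disease genes by propagating phenome-wide association
    study (PheWAS) derived -log10 p-value scores over a directed
    gene-dependency network with a damped PageRank-style iteration, and
    evaluates the resulting ranking: disease-database enrichment by Pearson
    chi-squared tests, top-of-list drug-target enrichment by a one-sided
    two-sample Kolmogorov-Smirnov test, hypergeometric over-representation
    with Benjamini-Hochberg correction, and candidate-agent prediction with
    clinical-support scoring. Includes an optional construction of the
    directed dependency network from expression data and a binary prognosis
    phenotype via conditional mutual information, and seeded synthetic-data
    generators with planted ground truth so the full pipeline can be exercised
    and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    withr,
    jsonlite,
    yaml,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PheWASRank-package.R'
    'drugs.R'
    'io.R'
    'methods.R'
    'network-inference.R'
    'pipeline.R'
    'rank.R'
    'simulate.R'
    'validation.R'
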