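Package: hicats
Title: Hybrid Imperialist Competition and Tabu Search for Gene Subset Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Wrapper feature selection for high-dimensional gene expression
    data using a binary imperialist competition algorithm hybridized with a
    tabu-search local refinement of each imperialist (HICATS). Candidate gene
    subsets are encoded as bit-vector "countries" grouped into empires; colonies
    are assimilated toward their imperialist by a Baldwinian difference-transfer
    move with random binary templates, and empires compete for colonies until
    the weakest collapse. Subsets are scored by a weighted combination of
    cross-validated classification accuracy (leave-one-out or stratified k-fold,
    with a pluggable classifier defaulting to a linear support vector machine)
    and a parsimony term rewarding small subsets. Includes a seeded synthetic
    expression-data generator with planted informative genes, convergence
    logging, an elitist best-so-far archive, a pure-ICA ablation mode, and
    delimited-text I/O for expression matrices and results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
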