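Package: activesvm
Title: Active Feature Selection of Minimal Gene Panels with Linear Support
    Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Iterative active-learning discovery of compact marker-gene panels
    for cell-state classification in bulk and single-cell expression data.
    Linear soft-margin support vector machines are trained on a growing gene
    set; only poorly classified cells are examined in full, and each next gene
    is chosen to maximize the rotation of the SVM margin. Provides min-cell and
    min-complexity acquisition strategies, class-balanced cell sampling,
    sparse/dense/on-disk expression stores with block access, comparison
    baseline selectors, and a planted-marker negative-binomial simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    e1071,
    kernlab,
    rpart,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
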