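Package: cswo
Title: Closest String with Outliers: Exact Solvers, Hardness Gadgets and
    Instance Generators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solvers for the CLOSEST STRING WITH OUTLIERS problem:
    given n equal-length strings, a Hamming radius d and an outlier budget
    k, find a center string within distance d of at least n - k inputs and
    identify the outliers.  Provides a fixed-parameter bounded search tree
    solver parameterized by (d, k), an exhaustive center-enumeration
    solver, and a subset-enumeration solver built on an exact 0/1
    integer-program formulation of closest string; wrappers minimize d or
    k.  Also includes the constructive CLIQUE-to-CSWO hardness reduction
    as an instance generator with clique decoding, seeded planted-center
    and random instance generators, FASTA and tokenized instance formats,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
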