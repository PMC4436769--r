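Package: coexdyn
Title: Time Dynamics of Gene Co-Expression Within Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the internal gene-gene co-expression structure of
    annotated protein complexes changes between a case and a control group
    across a time course. For each complex it builds per-(group, timepoint)
    upper-triangular Pearson correlation matrices and compares them two ways:
    a paired t-test on the average correlation level, encoded as a signed
    quadruplet over timepoints, and a normalized Euclidean matrix distance
    whose significance is assessed with a z-score against size-matched random
    gene sets. Includes readers for expression matrices, sample metadata,
    probe-gene maps and CORUM-style complex catalogs, ANOVA-based probe
    selection and collapse to gene level, a multivariate-normal synthetic
    data generator with planted correlation blocks, and a reporting layer
    that reproduces the quadruplet and distance/z-score tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
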