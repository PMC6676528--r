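Package: wgdfrac
Title: Branching-Process Inference of Polyploidy, Speciation and Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the creation and loss of duplicate gene pairs after whole-genome
    doubling or tripling as a discrete-generation Galton-Watson branching process in
    which the offspring distribution is reinterpreted as per-event survival of the r
    copies of each gene.  Provides closed-form expected counts of paralog and ortholog
    i-pairs and of unpaired genes, a seeded Monte-Carlo simulator of gene trees under
    event schedules and speciation scenarios, a generator of synthetic gene-pair
    similarity samples (mixtures of truncated normals whose means decay exponentially
    with event age), local-mode detection and constrained maximum-likelihood mixture
    fitting, and inversion of the pair-count expectations into survival probabilities
    and fractionation rates per million years.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
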