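Package: inphelix
Title: Beta-Helical Modelling and Ice-Nucleation Surface Analysis for
    Bacterial Ice Nucleation Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the tandem 16-residue repeat array of
    bacterial ice nucleation proteins, building idealized parallel
    beta-helix coordinate models from the repeats, assembling tyrosine-
    ladder-mediated dimers and offset multimers, mapping ordered-water
    density from superimposed trajectory frames, registering ordered-water
    sites against ideal hexagonal ice lattices, and evaluating the
    ice-active surface area of monomers and multimers against the critical
    ice-embryo area. Includes a synthetic-data module that generates
    repeat sequences and hydrated trajectories with known ground truth so
    every stage of the pipeline can be validated at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    bio3d,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
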