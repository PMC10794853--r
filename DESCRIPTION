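Package: masksketch
Title: Masked-Minimizer and Syncmer Sketching with Sequence-Specific
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Samples representative k-mer seeds from DNA sequences with
    minimizer, open/parameterized syncmer, and masked-minimizer schemes,
    and scores the resulting sketches by density, substitution
    conservation, window coverage, and the generalized sketch score
    (GSS).  Includes a bi-level optimizer that learns a sequence-specific
    k-mer ordering by gradient descent on differentiable sketch
    surrogates while greedily pruning the qualifying-offset mask to
    maximize GSS, plus simulators for uniform-random and
    homopolymer-rich test sequences and substitution-mutated homologs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
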