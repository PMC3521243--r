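Package: ligmap
Title: Mapping Small-Molecule Binding Data to Pfam-A Protein Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps measured small-molecule bioactivities to the Pfam-A domain
    that mediates binding, using a seed-domain heuristic: domain families that
    occur as the sole family of a protein with a qualifying binding-assay
    activity are treated as validated ligand-binding ("seed") domains, and
    activities against multi-domain proteins are assigned to the unique seed
    domain they contain. Includes validation machinery based on the overlap
    between annotated binding-site residues and domain boundaries, discrete
    power-law analysis of domain and ligand frequency spectra (maximum
    likelihood alpha/xmin estimation, Kolmogorov-Smirnov bootstrap
    goodness-of-fit, Vuong-style likelihood-ratio tests against lognormal,
    exponential and Weibull alternatives), principal component analysis of
    ligand descriptor space, a synthetic fixture generator with planted
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
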