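Package: minsize
Title: Min-System Oscillations and Cell-Size Control in Escherichia coli
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic 1-d reaction-diffusion simulation of the MinD/MinE
    pole-to-pole oscillation system in rod-shaped bacteria, with mid-cell
    occupancy scoring that maps the MinE/MinD expression ratio to the cell
    length permissive for FtsZ ring assembly. Couples that map to arabinose
    induction kinetics and a generational growth recursion to predict the
    transient delay in Z-ring formation and the monotonic rise of birth size
    after minE overexpression. Includes a synthetic mother-machine lineage
    generator and the single-cell trace statistics (65%-threshold ring timing,
    per-generation aggregates, sister-pair and adder statistics) needed to
    analyse such data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
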