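Package: pepspec
Title: Protease Substrate Specificity Profiling and Enzyme Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the substrate specificity and regulation
    of serine proteases. Implements reduction of positional-scanning synthetic
    combinatorial library (PSSCL) plate readouts to P4-P1 specificity matrices;
    a proteomics-based identification of cleavage sites (PICS) pipeline that
    digests a reference proteome in silico, locates semi-specific peptides,
    applies a fold-change acceptance filter and reconstructs P6-P6' cleavage
    windows with natural-abundance correction; position-weight-matrix log-odds
    scoring and scanning of candidate protein substrates; and enzyme-kinetic
    fitting (Michaelis-Menten, active-site burst titration, IC50 dose-response,
    inhibition-mechanism classification by AICc with Eadie-Hofstee diagnostics,
    and calcium-activation models). Seedable simulators generate every input
    the pipeline consumes together with truth records for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
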