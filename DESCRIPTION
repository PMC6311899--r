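Package: sigpath
Title: Signaling Pathway Inference from Scored Protein Interaction
    Networks and Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds background receptor-to-transcription-factor signaling
    paths from a confidence-scored protein-protein interaction network,
    identifies housekeeping genes from a multi-tissue expression panel,
    scores and ranks the pathways implied by a query expression profile,
    and estimates the false-positive rate of the pathway calls by gene
    label permutation.  Includes a synthetic-data generator with planted
    active pathways so the full pipeline can be exercised without any
    external database download, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
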