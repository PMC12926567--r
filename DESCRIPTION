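Package: allelescope
Title: Allele-Resolved Quantification of CRISPR Editing Outcomes at HBB
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies CRISPR editing outcomes at the beta-globin (HBB)
    locus into in-frame, early- and late-nonsense, large-deletion and
    loss-of-allele classes, and quantifies them with the assays used for
    dual-fluorescent reporter models of sickle cell gene correction:
    premature-stop (NS) codon mapping on the reconstructed coding sequence,
    allele attribution of long amplicon reads via a 3-nt GFP/BFP marker
    codon with a read-ratio loss-of-allele estimator, droplet digital PCR
    Poisson drop-off quantification with renormalization of amplicon
    sequencing fractions to total alleles, and 4 x 5 GFP/BFP fluorescence
    cluster gating linking genotype classes to phenotype summaries. A
    forward simulator generates cells, long reads, droplets and flow events
    with known truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
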