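Package: ozzooms
Title: Collagen Peptide Mass Fingerprinting of Australian Marsupials and Monotremes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Zooarchaeology by mass spectrometry (ZooMS) identification of
    Australian marsupial and monotreme skeletal remains from collagen type I
    peptide mass fingerprints. Bundles a reference panel of MALDI-TOF peptide
    marker masses and sequences for 24 taxa, computes monoisotopic peptide
    masses with hydroxyproline and deamidation modifications, performs in
    silico tryptic digestion, matches centroided peak lists against the panel
    under oxidation-pair and mass-collision ambiguity rules, classifies
    samples to the finest resolvable taxonomic rank, discovers candidate
    markers from homologous collagen chain sequences, and simulates seeded
    synthetic spectra and assemblages with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    xml2
VignetteBuilder: knitr
Config/testthat/edition: 3
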