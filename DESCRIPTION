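Package: selenoquant
Title: Absolute Selenoprotein Quantification by Species-Unspecific
    Isotope Dilution HPLC-ICP-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Heteroatom-tagged proteomics toolkit for the absolute
    quantification of selenoproteins in serum. Converts multi-isotope
    HPLC-ICP-MS chromatograms into selenium mass-flow traces via the
    species-unspecific online isotope-dilution equation (enriched 74Se
    post-column spike, 78Se/74Se ratio), integrates fixed retention
    windows into per-species selenium masses and concentrations, and
    assembles cohort speciation tables with aggregate statistics,
    percent composition and Se-atom stoichiometry conversion to protein
    concentration. Includes a forward simulator of online-IDA
    chromatograms with Poisson counting noise for end-to-end validation,
    and a bottom-up module for in-silico tryptic digestion, peptide mass
    matching, sequence-coverage scoring and b/y fragment ladders used to
    confirm selenoprotein identities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
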