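Package: glycomaldi
Title: Annotation and Differential Analysis of Permethylated N-Glycan
    MALDI-TOF Spectra, Including Sulfoglycomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for MALDI-TOF N-glycomics of permethylated glycans:
    a monoisotopic mass calculus for fully permethylated, optionally
    sulfated N-glycans and their singly charged ions (sodiated positive
    ions; sodium-salt negative ions for the sulfated pool), constrained
    composition enumeration and peak-list annotation with signal-to-noise
    filtering and under-permethylation / di-sulfation satellite flagging,
    glycosidic fragment enumeration with the diagnostic-ion decision logic
    that assigns 3-O-sulfated galactose from negative-mode MS/MS,
    TIC-normalized glycan-class profiles with two-sample t-test
    comparisons, and synthetic-data generators (spectra, paired cohorts,
    paired RPKM expression tables) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
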