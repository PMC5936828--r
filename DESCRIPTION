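Package: glycomer
Title: Glycomer Deconvolution and Annotation of Invertebrate N-Glycan MALDI Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for annotating MALDI-TOF mass spectra of permethylated and
    2-aminobenzamide (2-AB) labeled N-glycans, with an emphasis on the unusual
    core-chitobiose-modified (galactosylated core fucose) and O-methylated
    glycans found in flatworms. Provides monoisotopic mass bookkeeping for
    native, permethylated and 2-AB derivatized glycans; a condensed-IUPAC
    glycan structure parser; bounded composition enumeration for MS1 peak
    assignment; Domon-Costello B/Y fragment enumeration and deconvolution of
    isomeric glycans (glycomers) from complementary fragment-ion pairs;
    simulation of exoglycosidase and chemical treatments with decision-table
    linkage inference; GC-MS PMAA (partially methylated alditol acetate)
    linkage lookup; and a seeded synthetic-spectrum generator so the whole
    pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
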