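Package: nhkir
Title: Nomenclature Engine for Killer-Cell Immunoglobulin-Like Receptor
    Genes of Non-Human Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parses, validates and orders standardized KIR gene and allele
    designations for rhesus macaque, chimpanzee, orangutan and cattle;
    ships the registry of current designations with their previous names
    and accession identifiers; resolves legacy names to current ones; and
    assigns standards-conformant names to novel KIR coding sequences by
    classifying their differences from registered alleles into the
    non-synonymous, synonymous and non-coding digit tiers, applying the
    recombinant majority-locus rule, null-allele detection and provisional
    workshop gene flagging.  A seeded generator of KIR-like annotated
    sequences supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
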