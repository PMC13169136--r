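Package: derepms
Title: Diagnostic-Ion Dereplication of Phenolic Metabolites from Negative-Mode MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based annotation ("dereplication") of plant phenolics from
    negative-ion ESI-MS/MS peak lists. Implements hierarchical diagnostic-ion
    keys for acylquinic acids (backbone series, acid-anion markers, base-peak
    regiochemistry, diacyl ordering by loss-ion abundances), caffeoylhexaric
    acids (sequential caffeoyl-loss ladders and ester substituents of the
    leontopodic-acid type), phenolic-acid glycosides and sugar esters
    (cross-ring cleavages), and flavonoid glycosides (sugar neutral losses and
    aglycone lookup). Includes exact monoisotopic mass arithmetic for
    deprotonated and dimeric adducts, ppm windows, editable residue/sugar/
    aglycone registries, identification-confidence grading, percent-peak-area
    semi-quantitation, readers and writers for MSP/MGF and a tabular fixture
    dialect, a ground-truthed synthetic-spectrum generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
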