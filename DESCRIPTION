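Package: micontact
Title: Mutual-Information Coevolution Scores for Domain-Domain Contact
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes mutual information (MI) and its coevolution-score
    variants -- MIp (average product correction), MIc (coevolutionary
    pattern similarity correction), the triangle scores MI3D and MIp3D,
    and reduced-alphabet versions of each -- on paired-domain multiple
    sequence alignments, for predicting residue contacts between two
    protein domains.  Includes alignment sanitisation and masking,
    surface/buried and contact/non-contact residue annotation from
    atomic coordinates and solvent-accessibility tables, precision-recall
    and Matthews-correlation evaluation over percentile cutoffs,
    subsampling stability analysis, a binomial top-k enrichment test,
    and a synthetic paired-MSA generator with planted covarying columns
    and consistent structural annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
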