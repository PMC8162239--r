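Package: phosphoaudit
Title: Auditing Phosphosite Annotations Against a Reference Proteome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for auditing protein phosphorylation-site annotations
    drawn from pathway and PTM knowledgebases. Identifiers are harmonized
    to current primary accessions of a reference sequence catalog
    (secondary-accession mapping, obsolete and foreign-taxon removal,
    isoform stripping, reviewed-first one-to-one resolution); every site
    annotation is classified against canonical and isoform sequences as a
    match, isoform match, mismatch, closest-exact-match offset, or
    unmatched; coverage is summarized by pairwise intersection matrices,
    UpSet-style exclusive intersections, unique sets and set differences;
    experimental cell-line tables are filtered to single-sample
    publications and their per-sample database coverage computed; and
    unique protein sets are tested for term over-representation. A
    synthetic-data module generates catalogs, annotation sets, membership
    structures and experimental tables with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
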