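#!/usr/bin/env Rscript
# Stage 2 — identifier harmonization.
#
# Updates every identifier of the study's annotation sets to current,
# human, primary base accessions and reports how each bucket (kept, mapped
# secondary, obsolete, foreign taxon, unknown) is populated. The id_audit
# set contains every identifier the catalog knows about, so its report
# shows the full planted structure.

suppressMessages(library(phosphoaudit))

catalog <- read_catalog("results/study/catalog.fasta",
                        "results/study/catalog_ids.tsv")
names <- c("sites", "id_audit", paste0("db", 1:5))
tables <- list()
for (nm in names) {
  raw <- read_annotation_set(file.path("results/study", paste0(nm, ".tsv")),
                             nm)
  h <- harmonize_annotation_set(raw, catalog)
  cat("--", nm, ":\n")
  print(h$report)
  tables[[paste0("harmonization_", nm)]] <-
    cbind(database = nm, harmonization_fractions(h$report))
  write_annotation_set(h$set, file.path("results/study",
                                        paste0(nm, ".harmonized.tsv")))
}
write_tables(tables, "results/harmonize")
cat("harmonized sets written to results/study/*.harmonized.tsv;",
    "bucket tables to results/harmonize/\n")
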