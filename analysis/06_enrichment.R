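#!/usr/bin/env Rscript
# Stage 6 — over-representation of database-unique proteins.
#
# For each database, tests the proteins unique to it against the union of
# all databases' proteins (the background) using the hypergeometric upper
# tail, with Benjamini-Hochberg adjustment across terms. The synthetic term
# map groups proteins by membership signature, so terms aligned with a
# database's unique block should surface as enriched.

suppressMessages(library(phosphoaudit))

sets <- lapply(paste0("db", 1:5), function(nm) {
  read_annotation_set(file.path("results/study",
                                paste0(nm, ".harmonized.tsv")), nm)
})
prot <- element_sets(sets, "protein")
background <- unique(unlist(prot, use.names = FALSE))

truth <- jsonlite::fromJSON("results/study/truth.json")
term_map <- split(truth$membership$element, truth$membership$signature)

rows <- lapply(names(prot), function(nm) {
  uq <- unique_elements(nm, prot)
  res <- ora(uq, background, term_map)
  if (nrow(res)) cbind(database = nm, res) else NULL
})
tab <- do.call(rbind, rows)
sig <- tab[tab$significant, c("database", "term", "k", "K", "p", "q")]
cat("significant term enrichments (q <= 0.05):\n")
print(sig, row.names = FALSE)
write_tables(list(enrichment = tab), "results/enrichment")
cat("full enrichment table written to results/enrichment/\n")
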