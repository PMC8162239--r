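#!/usr/bin/env Rscript
# Stage 4 — cross-database set algebra.
#
# Computes, over the five harmonized protein databases: the pairwise
# intersection/coverage matrix, the UpSet-style exclusive intersections (the
# counts partition the union), the proteins unique to each database, and
# both orientations of the set-difference matrix.

suppressMessages(library(phosphoaudit))

sets <- lapply(paste0("db", 1:5), function(nm) {
  read_annotation_set(file.path("results/study",
                                paste0(nm, ".harmonized.tsv")), nm)
})
prot <- element_sets(sets, "protein")

pm <- pairwise_matrix(prot, prot)
ei <- exclusive_intersections(prot)
uq <- lapply(names(prot), unique_elements, prot)
names(uq) <- names(prot)
dm <- difference_matrix(prot, prot)

cat("union size:", attr(ei, "universe_size"), "proteins;",
    "global intersection:",
    sum(ei$count[ei$signature == paste(names(prot), collapse = "&")]), "\n")
cat("proteins unique to each database:\n")
print(lengths(uq))

write_tables(list(
  pairwise = data.frame(reference = rep(rownames(pm$count), ncol(pm$count)),
                        query = rep(colnames(pm$count),
                                    each = nrow(pm$count)),
                        count = as.integer(pm$count),
                        proportion = as.numeric(pm$proportion)),
  upset = as.data.frame(ei),
  unique_counts = data.frame(database = names(uq), n_unique = lengths(uq))),
  "results/coverage")
cat("coverage tables written to results/coverage/\n")
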