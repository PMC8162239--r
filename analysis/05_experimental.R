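#!/usr/bin/env Rscript
# Stage 5 — coverage of experimental cell-line phosphoproteomes.
#
# Filters the qPhos-style table to publications tagged with a single sample
# (a multi-sample publication cannot attribute its sites to one condition),
# ranks cell lines by distinct publication count, and computes each
# database's coverage of every cell line's measured proteins and sites.

suppressMessages(library(phosphoaudit))

rec <- read_experimental("results/study/experimental.tsv")
flt <- filter_single_sample(rec)
cat("PMIDs kept (single-sample):", length(flt$kept$pmid_samples),
    "| excluded (multi-sample):", length(flt$excluded$pmid_samples), "\n")
rk <- rank_samples(flt$kept)
print(rk)

dbs <- lapply(c("sites", paste0("db", 1:5)), function(nm) {
  read_annotation_set(file.path("results/study",
                                paste0(nm, ".harmonized.tsv")), nm)
})
prot_cov <- sample_coverage(flt$kept, dbs, "protein", top_k = 6)
site_cov <- sample_coverage(flt$kept, dbs, "site", top_k = 6)
cat("site-level coverage (proportion of each cell line's phosphosites):\n")
print(site_cov)

long <- function(m) {
  data.frame(sample = rep(rownames(m$count), ncol(m$count)),
             database = rep(colnames(m$count), each = nrow(m$count)),
             count = as.integer(m$count),
             proportion = as.numeric(m$proportion))
}
write_tables(list(ranking = rk, coverage_protein = long(prot_cov),
                  coverage_site = long(site_cov)), "results/experimental")
cat("experimental coverage tables written to results/experimental/\n")
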