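#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Builds the reference catalog stand-in (1,000 human proteins with isoforms,
# secondary/obsolete/foreign identifiers), plants 100 phosphosite
# annotations with known consistency categories, lays five databases over a
# fixed exclusive-intersection structure, and writes a qPhos-style
# experimental table for six cell lines. Everything downstream stages read
# lives under results/study/.

suppressMessages(library(phosphoaudit))

seed <- 1234L
spec <- synthetic_spec(seed = seed)
sim <- simulate_study(spec, "results/study")

cat("Generated study (seed ", seed, "):\n", sep = "")
print(sim$catalog)
cat("planted sites by category:\n")
print(table(sim$truth$sites$category))
cat("membership databases:", paste(spec$membership_names, collapse = ", "),
    "| planted union:", sum(unlist(spec$membership_vector)), "proteins\n")
cat("experimental PMIDs:", length(sim$experimental$records$pmid_samples),
    "of which multi-sample:", length(sim$truth$experimental$multi_pmids), "\n")
cat("files written under results/study/\n")
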