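# phosphoaudit

Pathway and PTM knowledgebases disagree about phosphorylation. The same
protein can carry a phosphoserine annotation at position 495 in one resource
and nothing closer than position 490 in the reference sequence; identifiers
drift as accessions are merged, retired or re-curated; and each database
covers a different slice of the phosphoproteome. Anyone mapping a
phosphoproteomics experiment onto pathway knowledge inherits all of these
inconsistencies at once.

`phosphoaudit` is an R package for auditing phosphosite annotations against
a reference sequence catalog. It is aimed at curators of PTM resources and
at analysts who need to know, before mapping an experiment, how consistent
and how complete their chosen knowledgebase actually is. The pipeline has
five stages, each usable on its own:

1. **Harmonization** — identifiers are normalized to current, human,
   primary base accessions: isoform suffixes stripped, secondary accessions
   mapped to their primary, obsolete and foreign-taxon identifiers removed,
   and ambiguous foreign-identifier mappings resolved one-to-one
   (reviewed entries first, then longest canonical sequence).
2. **Consistency** — every site annotation (accession, residue, 1-based
   position) is classified against the canonical and isoform sequences as a
   *canonical match*, *isoform match*, *mismatch* (another phosphorylatable
   residue occupies the position), *offset* (nearest exact occurrence at a
   recorded signed distance, binned 1/2/3/+), or *unmatched*. The signed
   offset is annotated minus matched position, so initiator-methionine
   cleavage shows up as −1.
3. **Coverage** — pairwise intersection/coverage matrices, UpSet-style
   exclusive intersections (which partition the union), per-database unique
   sets and set differences, at protein or exact site-triple level.
4. **Experimental mapping** — qPhos-style tables are filtered to
   publications tagged with a single sample (multi-sample publications
   cannot attribute sites to a condition), cell lines are ranked by
   publication count, and per-cell-line database coverage is computed at
   protein and site level.
5. **Enrichment** — proteins unique to a database are tested for term
   over-representation against the union of all databases
   (hypergeometric upper tail, Benjamini–Hochberg adjustment).

Because the original database downloads are not redistributable, the
package ships a synthetic-data module (`synthetic_spec()`,
`simulate_study()`) that generates catalogs, annotation sets, membership
structures and experimental tables with planted ground truth; every stage
of the pipeline is verified by recovering what was planted, exactly.

## Worked example

Classify four annotations on a 121-residue protein whose canonical sequence
starts with Met and has S60, T100 and Y30, plus a Met-cleaved isoform:

```r
library(phosphoaudit)
canon <- paste0("M", strrep("A", 120))
substr(canon, 60, 60) <- "S"; substr(canon, 100, 100) <- "T"
substr(canon, 30, 30) <- "Y"
rec <- sequence_record("P12345", canon,
                       isoforms = c("P12345-2" = substr(canon, 2, 121)))
sites <- data.frame(accession = "P12345",
                    residue = c("S", "T", "S", "Y"),
                    position = c(60L, 100L, 59L, 45L))
cls <- do.call(rbind, lapply(1:4, function(i) classify_site(sites[i, ], rec)))
cls
#>   accession residue position        category matched_in matched_position
#> 1    P12345       S       60 canonical_match  canonical               60
#> 2    P12345       T      100 canonical_match  canonical              100
#> 3    P12345       S       59   isoform_match   P12345-2               59
#> 4    P12345       Y       45          offset  canonical               30
#>   signed_offset magnitude_bin
#> 1             0          <NA>
#> 2             0          <NA>
#> 3             0          <NA>
#> 4            15             +
summarize_consistency(cls)
#> consistency_summary: 4 sites; 50.0% consistent; 1 isoform matches;
#> 0 mismatches; offsets 1=0 2=0 3=0 +=1 ; 0 unmatched
```

S60 and T100 sit where annotated; S59 is the same serine counted on the
Met-cleaved isoform's coordinates, so it matches the isoform at position 59;
Y45 is nowhere near an annotated tyrosine, and the nearest one (Y30) is 15
residues away — an offset in the "+" bin. The summary counts 2 of 4 sites
(50%) as consistent: isoform matches are excluded from the numerator but
kept in the denominator.

## The analysis workflow

`analysis/01_simulate.R` through `analysis/06_enrichment.R` run the whole
audit as a narrative over a generated study (1,000 proteins, 100 planted
sites, five databases, six cell lines), writing every table under
`results/`. Each script prints what it found; stage 3, for example, reports
the planted 60/10/5/20/5 category split back exactly, with the offset sign
split showing the −1 (Met-cleavage-like) majority. `run_audit()` performs
the same stages in one call over any set of input files and writes a
combined report with a manifest.

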