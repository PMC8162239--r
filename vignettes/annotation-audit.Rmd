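---
title: "Auditing phosphosite annotations: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing phosphosite annotations: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoaudit)
```

## The problem

A phosphosite annotation is the claim that a particular residue of a
particular protein is phosphorylated: an accession, a residue letter, and a
1-based position. Knowledgebases accumulate these claims from curation and
text mining, and the claims decay: accessions are merged or retired,
positions are copied from cleaved or isoform coordinate systems, and
residues are transcribed wrongly. `phosphoaudit` quantifies this decay by
checking every annotation against a reference sequence catalog, and
characterizes how differently resources cover the proteome and the
phosphoproteome.

Site identity throughout is the exact triple (base accession, residue,
position). No sequence-window (±k-mer) standardization is attempted: the
audit measures annotations as resources state them, and window realignment
would mask exactly the inconsistencies it is meant to surface.

## Identifier harmonization

All resources are normalized to one namespace before any comparison:

* **Isoform stripping.** `"P04637-2"` becomes `"P04637"`. Stripping happens
  *before* the identifier update, because secondary and obsolete status is
  defined on base accessions; the alternative order is not expressible
  against the bookkeeping tables at all. Positions are deliberately *not*
  renumbered when an isoform annotation is reassigned to its base — there
  is no general renumbering rule without an alignment — so any coordinate
  damage this causes surfaces downstream as a mismatch or offset rather
  than being silently hidden.
* **Update.** Each base is routed to exactly one outcome: `primary`
  (current record of the reference taxon), `secondary_mapped`,
  `obsolete_dropped`, `taxon_dropped`, or `unknown_dropped`. Outcomes
  partition the distinct inputs; the report carries the full per-input
  table so conservation is checkable, and sites whose accession is dropped
  are dropped with it.
* **One-to-one resolution.** When a foreign identifier (RefSeq, Entrez,
  KEGG id) maps to several accessions, `resolve_foreign_id()` keeps the
  reviewed subset if non-empty, then the longest canonical sequence. Ties
  between equally long reviewed candidates break to the lexicographically
  smallest base — the rule itself does not determine a winner there, and a
  deterministic tie-break keeps runs reproducible.

## The consistency classification

For a site (residue $r$, position $p$) on a record with canonical sequence
$c$ and isoforms $i_1, i_2, \dots$ (catalog order), `classify_site()`
applies this precedence:

1. **canonical match** — $c[p] = r$;
2. **isoform match** — $i_k[p] = r$ for the first such $k$;
3. **mismatch** — $c[p]$ is a *different* phosphorylatable residue;
4. **offset** — the occurrence of $r$ in $c$ minimizing $|p - p'|$, with
   signed offset $p - p'$ recorded;
5. **isoform mismatch, then isoform offset** — searched only when $r$ is
   absent from the canonical sequence entirely;
6. **unmatched.**

A position beyond the canonical length triggers no mismatch or offset
search on the canonical: such a site is an isoform match or unmatched.

Two conventions deserve justification, because the classification rule
leaves them genuinely open:

* **Precedence of isoform search.** Isoforms are described as searched
  "for the same criteria" once the canonical fails, but per-database
  summaries conventionally report only isoform *matches*. We therefore let
  an isoform match outrank a canonical mismatch/offset (it is the stronger
  statement: the residue exists exactly where annotated, on some sequence
  of the gene product), while isoform mismatches and offsets are reachable
  only when the canonical cannot produce any verdict because the residue
  does not occur in it at all. This keeps the summary reportable in the
  conventional layout while still honouring the isoform search.
* **Sign and ties.** The signed offset is annotated minus matched, so an
  annotation expressed on initiator-Met-cleaved coordinates (every
  downstream position one too small) classifies with offset $-1$. When two
  occurrences are equidistant, the later one — the negative offset — wins,
  because Met cleavage is the dominant known systematic shift; the
  magnitude, which is what the histogram bins, is unaffected by this
  choice.

A mismatch requires the occupying residue to belong to the
phosphorylatable set (default S, T, Y; configurable, e.g. to add
histidine). Any other occupant falls through to the offset search: a
glycine at the annotated position is evidence of a coordinate problem, not
of a competing phosphosite.

The summary counts only canonical matches as "consistent": isoform matches
are excluded from the numerator but retained in the denominator, as are
unmatched sites — the percentage answers "what fraction of all annotated
modified residues is correct as stated against the canonical sequence".
The offset histogram bins magnitudes 1, 2, 3 and "+" (≥ 4); signed values
are kept in the per-site table.

Degenerate inputs: an empty classification list yields an all-zero summary
with the percentage defined as 0; `residue_at()` on a position past the
sequence end returns `NA` rather than erroring, and positions below 1 are
rejected at parse time into the rejects report.

## Set algebra and experimental coverage

Coverage of a reference set $R$ by a query $Q$ is $|R \cap Q| / |R|$.
Exclusive (UpSet-style) intersections assign each element of the union to
exactly the subset of resources containing it; the counts partition the
union and this identity is asserted on every run. The minimum-count filter
(mirroring the practice of hiding overlaps below some size in plotted
UpSets) is a display option only — stored tables always contain every
signature.

Experimental tables are filtered at PMID granularity: a publication tagged
with two samples has *all* its sites excluded, the strict reading of
"publications and inherently their sites". Per-cell-line protein sets are
derived from the sites' accessions — a protein is measured in a sample iff
at least one of its sites is — because site-level resources have no
independent protein column worth trusting. Site-level coverage requires
exact triple equality, which is why a protein-level hit need not be a
site-level hit.

## Over-representation

Enrichment of a query set (here: proteins unique to one database) against
a background (the union of all databases' proteins) uses the one-sided
hypergeometric upper tail, $P[X \ge k]$ — the standard ORA formulation —
with Benjamini–Hochberg adjustment across tested terms. Both raw and
adjusted values are reported so either reading is available. Term maps
arrive pre-flattened (two-column TSV or GMT); no ontology propagation is
performed.

## The synthetic study

`synthetic_spec()` fixes the study conditions; its defaults are the
package's standing choices and are not tuned per run:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 1,000 | large enough that planted fractions are exact after rounding, small enough to audit in seconds |
| `length_range` | 200–600 | typical span of human protein lengths |
| `isoform_count_range` | 0–2 | most entries have few annotated isoforms |
| secondary / obsolete / foreign fractions | 0.10 / 0.05 / 0.05 | identifier churn at the scale resources actually exhibit |
| category counts | 60 / 10 / 5 / 20 / 5 | matches dominate real resources; offsets and isoform matches are the informative minority |
| offset list | eight −1s among 20 | the −1 (Met-cleavage-like) shift dominates real offset spectra |
| `multi_sample_fraction` | 0.2 | a visible minority of publications span conditions |
| cell-line labels | HeLa, HEK293, HeLa S3, Jurkat, MCF-7, MCF-10A | the commonly profiled lines |

Sequences are i.i.d. uniform over the 20 amino acids: recovery tests need
*structure*, not compositional realism, and uniform letters make the
planted constraints easy to enforce and verify. What the generator
emulates is the statistical shape of the audit's inputs — identifier
churn, category mixtures, exclusive-intersection vectors, multi-sample
tagging. What it does not emulate: real sequence composition, real
database content, kinase–substrate structure, or pathway topology. Passing
recovery tests therefore demonstrates that the pipeline measures what it
claims to measure, not that any particular real resource has a particular
consistency level.

Planting edits sequences to enforce each category *and* the absence of any
higher-precedence classification: one site per record; planted offsets
clear a window of radius $|m| - 1$ of the annotated residue plus the
equidistant tie position before placing the residue at the planted signed
distance; isoform and mismatch plants block all isoforms at the annotated
position. A final verification pass re-classifies every planted site and
stops with an error on any disagreement, so recovery is exact by
construction, never statistical. Infeasible specifications (an offset
magnitude not fitting the shortest sequence, more planted sites than
records) are rejected before generation. Because planting must edit
sequences, `plant_sites()` returns the edited catalog alongside the sites
and truth; classification must use that catalog.

The membership databases draw their elements from human accessions *not*
hosting planted sites, so the exclusive-intersection recovery cannot be
contaminated by harmonization effects; a consequence is that, in the
generated study, the protein-membership databases and the site-bearing set
are disjoint, and experimental coverage against the membership databases
is structurally zero while coverage against the site-bearing set is one.

## Determinism and problem sizes

Every generator takes a seed and is fully deterministic given it; the
audit writes tables with sorted rows and a JSON mirror, so identical
inputs give byte-identical reports. The shipped analysis scripts and the
test suite run the full study at 1,000 proteins with 100 planted sites,
and the oracle comparisons use 10,000 random sequences for the
nearest-occurrence scan, five sets for the signature enumeration, and
backgrounds of at most 12 for the factorial ORA oracle — sizes at which
the independent oracles are exhaustive or near-exhaustive while the whole
suite completes in about a minute.

## Known limitations

* No correction or repair of inconsistent annotations is attempted; the
  audit reports, it does not fix.
* Isoform reassignment without renumbering (see above) deliberately
  converts a coordinate-system problem into a visible
  mismatch/offset signal.
* The one-to-one resolution rule discards genuinely one-to-many gene
  products; this mirrors the harmonization policy it audits rather than a
  biological judgement.
* Duplicate annotations at one position with conflicting residue letters
  within one resource are kept as distinct triples; the rejects report and
  per-site table surface them, and no collapsing rule is imposed.
* The experimental module does not stratify by treatment or condition
  beyond the sample label, and does not use quantitative intensities.
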