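---
title: "Methods: conservation statistics, module completeness, and the core-genome tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation statistics, module completeness, and the core-genome tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangrove)
```

pangrove implements the analysis and query core of a comparative-genomics
workbench for annotated bacterial genomes: from GenBank flat files to an
orthology-centric view of gene conservation, metabolic module completeness,
a core-genome species tree, neighborhood/Circos comparison data, and a
searchable SQLite result store. This vignette explains the models and
procedures, the parameters that matter, and the design decisions taken where
the problem admitted more than one reasonable answer.

## Input model

A genome is a set of contigs plus a feature table. Coordinates are stored
0-based half-open internally and converted from GenBank's 1-based inclusive
convention at the parsing boundary, which keeps interval arithmetic (window
clipping, overlap tests, coding-density unions) free of off-by-one cases.
Strands are `+1`/`-1`. Compound (`join`) locations concatenate their exons
in feature order and are flagged; the flat span from first to last exon is
used for display windows. Partial-feature markers (`<`, `>`) are stripped:
at desk scale we prefer a complete, slightly optimistic feature table over
dropped genes at contig ends.

A CDS that carries a `/translation` qualifier keeps it verbatim — annotation
pipelines sometimes emit non-standard translations (selenocysteine,
programmed frameshifts) and silently re-translating would erase that signal.
A CDS without the qualifier is translated with the genetic code named by
`/transl_table`, defaulting to the bacterial/archaeal table 11, with the
trailing stop removed. Features flagged `/pseudo` become pseudogenes and
never carry a protein; internal stops are tolerated only there.

Locally assembled genomes often reuse locus tags. `sanitize_identifiers()`
repairs collisions by appending `_dupN` with the smallest `N` that avoids a
further collision, scanning genomes in input order, so the repair is
deterministic and idempotent and the rename map is a complete audit trail.

## Orthology

The unit of every conservation statistic is the orthogroup. Production data
sets should use a dedicated orthology tool and feed its tab-separated
output to `read_orthogroup_table()`; genes the table omits are appended as
singleton groups so that downstream statistics always account for every
gene, and the policy is recorded on the object.

For self-contained work at test scale, `infer_orthogroups()` provides the
classical reciprocal-best-hit construction: all inter-genome protein pairs
are aligned locally under BLOSUM62 with affine gaps (open 11, extend 1 —
the community default scoring), the best hit per query passing 30% identity
and 50% coverage of the shorter sequence is kept, reciprocal best hits
become edges, and orthogroups are the connected components of that graph.
Ties on alignment score are broken by lexicographic locus tag and genomes
are processed in sorted order, so the partition is deterministic and
invariant under input order. This is deliberately *not* an MCL-style graph
clustering: it is a transparent, testable stand-in whose behaviour is exact
on low-divergence families, while the external tool remains pluggable.

Percent identity is computed from a global alignment under the same scoring
as `100 * matches / (matches + mismatches)` — i.e. over the aligned columns
where neither side is a gap. Field tools rarely state their identity
denominator; this choice is symmetric, bounded in [0, 100], and excludes
terminal-gap artifacts, but note that values are not comparable to
definitions that divide by the shorter sequence length.

## Conservation statistics

The presence matrix holds copy numbers (orthogroup × genome); "presence"
everywhere means copy number ≥ 1, as no higher threshold is meaningful for
desk-scale data. From it derive:

* **Accumulation curves.** For each of `n_orders` (default 100) seeded
  random genome orderings, pan(k) counts groups present in at least one of
  the first k genomes and core(k) those present in all of them; means are
  reported per k and the seed (default 42) is kept in the output so any
  curve can be reproduced. For ≤ 8 genomes an exhaustive mode enumerates
  all G! orderings, which the tests compare against independent brute
  force.
* **Occupancy spectrum.** The histogram of orthogroups by the number of
  genomes containing them; the j = G bin is the core size, the j = 1 bin
  the singleton count.
* **Venn partitions.** For 2–6 chosen genomes, each group present in the
  subset is assigned to the exact region matching the set of genomes that
  contain it; the six-set cap mirrors what Venn renderers can draw, not a
  computational limit.
* **Differential queries.** Groups present in every genome of an include
  set and absent from an exclude set; a genome in both sets yields an empty
  result by construction. A `min_fraction` argument relaxes "every" to a
  fraction when draft genomes make strict conservation too brittle.

## KEGG module completeness

Metabolic modules are written in the KEGG definition language: spaces
separate consecutive steps, commas separate interchangeable alternatives,
`+` joins the subunits of a complex, a leading `-` marks an optional
subunit, `--` stands for a reaction with no known ortholog, and parentheses
group. The parser is a recursive-descent grammar with operator binding
`+`/`-` > `,` > space, reporting the character position of any error.

Completeness is evaluated recursively. An atom scores 1 when its KO is
present in the genome (presence is per genome, not per pathway position).
A complex scores 1 only when every non-optional subunit scores 1 — a
partially assembled complex is not functional. Alternatives take the
maximum of their branches. A step sequence takes the *arithmetic mean* of
its steps, which is what makes the reported completeness a fraction: a
genome with three of four steps of a linear pathway scores 0.75. The
fractional-mean choice for steps and the treatment of `--` as satisfied
(it denotes a reaction nobody has an ortholog for; `gap_value = 0` is
available) are the two semantic decisions the language itself leaves open;
both are therefore covered by an exhaustive truth-table oracle in the test
suite, over all 2^n KO subsets of hundreds of random definitions. Nested
module atoms (M numbers) are resolved recursively when their definitions
are supplied and count as satisfied only when fully complete; unresolvable
ones count as unsatisfied with a warning.

Annotation propagation implements the orthogroup-sharing rule: a gene with
no direct annotation for KO k is credited with k whenever an orthogroup
mate carries k directly. Propagated entries always cite their source group,
never feed further propagation (only direct entries seed the rule), and are
recomputed from the direct set on every call, making the operation
idempotent. Completeness can be computed with or without propagated KOs;
the propagated value is cell-wise ≥ the direct value, which the tests
verify together with the exact set of cells each planted case flips.

## Functional category profiles

COG/KEGG category profiles count, per genome, the genes carrying each
category. A gene with several categories counts once *per category*, so
count columns may sum above the number of annotated genes — the standard
COG reporting convention, recorded in the output attributes. Proportions
divide by the total number of genes in the genome (not annotated genes
only; the alternative denominator is a matter of slicing the same matrix)
and include an explicit `unannotated` row so each genome's genes are fully
accounted for.

## Core selection and the species tree

The species tree is built from orthogroups that are single copy wherever
present: any group with a 2+-copy genome is excluded outright, since
paralogy breaks the orthology assumption of concatenation. Because draft
assemblies lose genes, presence in all G genomes can be relaxed to
G − `max_missing`; selections are nested in `max_missing`, which the tests
check by brute force.

Per-group alignments are concatenated into a super-alignment with all-gap
padding for missing genomes and partition bookkeeping that slices back to
the originals. The default aligner ("identity") requires equal-length
members — exactly what the substitution-only fixture generator produces —
and `aligner = "mafft"` shells out to a PATH mafft for real, indel-bearing
families. Distances are identity distances with pairwise deletion (columns
where neither row is gapped, per pair), which is robust to the block-gap
pattern that missing genes create; complete deletion would discard every
partition any genome lacks. The tree is classical neighbor-joining.
Negative branch lengths, which NJ produces on non-additive input, are
clamped to zero with the deficit moved to the sister branch, preserving
path lengths as far as possible; on additive input the tree reproduces the
distance matrix exactly (tested to 1e-9). Maximum-likelihood inference is
intentionally out of scope — the NJ path exists so the species-tree
contract is testable offline, and an external tree can replace it wherever
a Newick string is consumed.

## Region and Circos comparison data

`compare_regions()` extracts the window `anchor ± window_bp` (default
8000 bp, a typical operon scale) around a gene and around its ortholog in
each target genome, flipping tracks whose anchor ortholog lies on the
opposite strand so homologous regions read in the same direction — the flip
mirrors display coordinates within the window and is an involution. Links
join features of consecutive tracks sharing an orthogroup and carry percent
identity; genomes with several orthologs contribute the first by
coordinate, and genomes with none are skipped with a notice.
`circos_tracks()` produces per-CDS rings for a reference genome: GC
percent, best-homolog identity per comparison genome (homology = shared
orthogroup), strand, contig boundaries, and the homolog-count histogram.
Identity values are emitted raw; binning and color scales belong to
renderers.

## Search language

The search bar grammar accepts bare terms (case-insensitive substring match
over locus tag, gene name, product, genome name, annotation ids, feature
kind), `*` as the only wildcard, quoted phrases, `field:` prefixes (which
match whole tokens — a prefix search like `locus_tag:GEN02` deliberately
misses unless `*` is added), and NOT > AND > OR with parentheses and
implicit AND on adjacency. The engine is checked against per-record brute
force on random ASTs, plus double-negation and De Morgan identities.

## Result store

All results land in a single SQLite file: genomes, contigs, genes,
orthogroups and memberships, annotations with provenance, module
definitions and completeness, Newick trees, and a `run_metadata` table
capturing the schema version and every parameter (seed, `n_orders`,
thresholds, orthology source), so any figure-ready output is reproducible
from the store alone. Referential integrity is checked before writing.
Deliberately absent from the metadata: wall-clock timestamps, so that
rebuilding from identical inputs yields identical row sets. Archives are
gzip tars holding the database plus a JSON manifest (schema version, tool
version, md5); import verifies the checksum, refuses newer schema versions
outright, and never installs a partially imported store.

## The synthetic data generator

`generate_fixture()` plants ancestral random proteins (60–120 aa), evolves
each genome by per-residue substitutions drawn from BLOSUM62-favored
exchanges (default divergence 0.05 — closely related strains), applies
family loss (default 0.10), optional duplication and pseudogenization,
back-translates with a fixed codon per amino acid, and lays genes on one
contig per genome with 100 bp fixed-composition spacers, emitting valid
GenBank files plus truth tables: the planted partition, KO/COG
assignments, planted propagation cases (genes of annotated families with
their direct KO withheld, at rate 0.15), module definitions, and expected
per-genome completeness computed by a self-contained string-rewriting
evaluator that shares no code with the package's parser. Everything is a
deterministic function of the seed.

What the generator does *not* emulate — rearrangements, horizontal
transfer, indels, contig fragmentation, annotation noise — bounds what
green tests mean: they certify the statistics, the language semantics, and
the plumbing exactly, not the behaviour of orthology inference on deeply
diverged or rearranged real genomes. For those, use the external-tool
ingestion path.

## Problem sizes and numerical notes

The test suite and the acceptance script run on 3–6 genomes with 8–20
families, exhaustive enumeration up to 4 genomes (24 orderings) and up to
2^6 KO subsets per definition — sizes at which every brute-force oracle is
exact and the whole suite completes in about a minute. Ties in best-hit
selection and NJ agglomeration are broken lexicographically; distances use
pairwise deletion and error out on a pair with zero comparable columns
rather than imputing; empty cores raise an explicit error suggesting a
larger `max_missing` rather than returning an empty tree.
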