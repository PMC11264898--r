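# pangrove

Comparative genomics of annotated bacterial genomes, as a library and a thin
command-line tool. pangrove takes GenBank flat files (e.g. Prokka/Bakta/PGAP
output) and turns them into an orthology-centric, queryable picture of a
genome set, for microbiologists comparing a handful to a few dozen strains:

* **Ingest** — GenBank parsing, identifier de-duplication, protein/nucleotide
  extraction, genome summaries (GC%, coding density).
* **Orthology** — ingestion of standard orthogroup tables, plus a built-in
  deterministic reciprocal-best-hit inference (BLOSUM62, gap 11/1) for
  self-contained small data sets.
* **Pan-genome statistics** — over the orthogroup × genome copy-number
  matrix: core/pan accumulation curves averaged over seeded genome
  orderings, the occupancy spectrum (orthogroups by number of genomes,
  singletons at 1, core at G), Venn partitions for 2–6 genomes, and
  differential queries ("present in these genomes, absent from those").
* **KEGG module completeness** — a full parser for the KEGG module
  definition language (steps, `,` alternatives, `+` complexes, `-` optional
  subunits, `--` gaps, parentheses) and a recursive evaluator: complexes
  are all-or-nothing, alternatives take the best branch, step sequences
  average, so completeness is a fraction in [0, 1]. Genes lacking a direct
  KO inherit it from orthogroup mates (annotation propagation, with
  provenance).
* **Core-genome phylogeny** — relaxed single-copy core selection
  (`max_missing` genomes may lack a group; paralogous groups always
  excluded), concatenated alignment, pairwise-deletion identity distances,
  neighbor-joining with non-negative branch lengths.
* **Region & Circos data** — gene-neighborhood comparison tracks with
  strand normalization and identity-weighted ortholog links; per-CDS rings
  (GC%, best-homolog identity per genome, strand, contig, homolog counts)
  as plot-ready JSON.
* **Search** — a query language with wildcards, quoted phrases, `field:`
  prefixes and NOT/AND/OR over genes, products, genomes and annotations.
* **Store** — everything lands in one SQLite file with run metadata;
  portable gzip archives with checksummed manifests round-trip losslessly.
* **Synthetic data** — a seeded generator plants gene families with known
  orthology, annotations and module completeness, so the entire pipeline is
  testable offline; truth tables ship alongside the generated GenBank files.

## Worked example

```r
library(pangrove)

# a 4-genome synthetic data set with known truth
fx <- generate_fixture(fixture_config(n_genomes = 4, n_families = 12,
                                      divergence = 0.05, loss_rate = 0.15,
                                      seed = 401), out_dir = "demo")

res <- run_pipeline("demo",
                    orthogroups = "demo/orthogroups.tsv",
                    ko = "demo/ko.tsv", cog = "demo/cog.tsv",
                    modules = "demo/modules.tsv",
                    max_missing = 1, seed = 42, out_db = "demo/store.sqlite")

res$spectrum
#> 1 2 3 4
#> 0 2 6 4
```

Twelve orthogroups: none private to one genome, two shared by a pair, six in
three genomes, and a four-genome core of four — gene loss at rate 0.15 has
eroded the core, exactly what the occupancy spectrum is for.

```r
res$summaries[, c("genome_id", "total_length", "gc_percent", "n_cds", "coding_density")]
#>       genome_id total_length gc_percent n_cds coding_density
#> GEN01     GEN01         3884      38.77    10         0.7168
#> GEN02     GEN02         3965      38.64    10         0.7226
#> GEN03     GEN03         3135      38.66     8         0.7129
#> GEN04     GEN04         3767      38.28    10         0.7080

round(res$completeness$completeness, 3)
#>        GEN01 GEN02 GEN03 GEN04
#> M00001     1  1.00  0.75     1
#> M00002     1  0.50  0.50     1
#> M00003     1  0.75  0.50     1
```

Module M00002 is half-complete in GEN02: one of its two steps is satisfied.
The per-cell provenance (which KOs were direct, which propagated from
orthogroup mates) is in `res$completeness$results`.

```r
ape::write.tree(res$tree)
#> (GEN03:0.0539,GEN02:0.0634,(GEN01:0.0414,GEN04:0.0396):0.0014);

venn_partitions(res$matrix, c("GEN01", "GEN02"))
#>       GEN01       GEN02 GEN01&GEN02
#>           2           2           8

idx <- build_search_index(res$genomes)
execute_query(parse_query('"family 003" AND NOT genome:GEN02*'), idx)[, 1:2]
#>   genome_id  locus_tag
#> 1     GEN01 GEN01_0002
#> 2     GEN03 GEN03_0002
#> 3     GEN04 GEN04_0002
```

The same store can be driven from a shell via the thin CLI in
`inst/cli/pangrove`:

```sh
pangrove run --input demo --out demo/store.sqlite --orthogroups demo/orthogroups.tsv
pangrove stats --db demo/store.sqlite --what spectrum
pangrove query --db demo/store.sqlite --expr 'fam003 AND NOT GEN02*'
pangrove export --db demo/store.sqlite --out demo/results.tar.gz
```

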