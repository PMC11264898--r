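# Shared fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- maker()
  .fx_cache[[name]]
}

# small 4-genome fixture with losses, used by pangenome/kegg/store tests
fx_small <- function() cached("small", function()
  generate_fixture(fixture_config(n_genomes = 4, n_families = 12,
                                  divergence = 0.05, loss_rate = 0.15,
                                  seed = 401)))

# 5-genome, 20-family fixture for orthology recovery
fx_recovery <- function() cached("recovery", function()
  generate_fixture(fixture_config(n_genomes = 5, n_families = 20,
                                  divergence = 0.08, loss_rate = 0,
                                  paralog_rate = 0, seed = 402)))

# 6-genome fixture written to disk, with truth tables, for pipeline tests
fx_pipeline_dir <- function() cached("pipeline_dir", function() {
  dir <- file.path(tempdir(), "pangrove_fx_pipeline")
  unlink(dir, recursive = TRUE)
  fx <- generate_fixture(fixture_config(n_genomes = 6, n_families = 20,
                                        divergence = 0.05, loss_rate = 0.1,
                                        seed = 403), out_dir = dir)
  list(dir = dir, fx = fx)
})

# a hand-written two-gene GenBank record exercising both strands, a pseudo
# gene, and a CDS without a /translation qualifier
gbk_text_minimal <- function() {
  seqs <- paste0(
    "ATGAAACTGGTTTAA",                 # + strand CDS at 11..25 (1-based)
    strrep("ACGT", 5),
    oracle_revcomp("ATGGGCCCGTGGTAA"), # - strand CDS at 46..60
    strrep("ACGT", 5))
  contig <- paste0(strrep("ACGT", 2) , "GG", seqs)  # 10 bp lead-in
  fmt_origin <- function(s) {
    pos <- seq(1, nchar(s), 60)
    paste(vapply(pos, function(p) {
      chunk <- substr(s, p, min(p + 59, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      sprintf("%9d %s", p, tolower(paste(tens, collapse = " ")))
    }, ""), collapse = "\n")
  }
  paste0(
    "LOCUS       CTGA             ", nchar(contig),
    " bp    DNA     linear   BCT 01-JAN-2000\n",
    "DEFINITION  Minimal test genome.\n",
    "ACCESSION   CTGA\n",
    "FEATURES             Location/Qualifiers\n",
    "     source          1..", nchar(contig), "\n",
    "                     /organism=\"Testus minimus\"\n",
    "     CDS             11..25\n",
    "                     /locus_tag=\"TST_0001\"\n",
    "                     /product=\"forward protein\"\n",
    "     CDS             complement(46..60)\n",
    "                     /locus_tag=\"TST_0002\"\n",
    "                     /gene=\"revA\"\n",
    "                     /product=\"reverse protein\"\n",
    "     CDS             66..74\n",
    "                     /locus_tag=\"TST_0003\"\n",
    "                     /product=\"broken protein\"\n",
    "                     /pseudo\n",
    "ORIGIN\n",
    fmt_origin(contig), "\n//\n")
}

write_gbk_minimal <- function() {
  path <- tempfile(fileext = ".gbk")
  writeLines(gbk_text_minimal(), path)
  path
}

# presence matrices with controlled shape
random_matrix <- function(n_og, n_genomes, seed, p_present = 0.6,
                          max_copies = 3) {
  set.seed(seed)
  m <- matrix(ifelse(stats::runif(n_og * n_genomes) < p_present,
                     sample(seq_len(max_copies), n_og * n_genomes, replace = TRUE),
                     0L),
              nrow = n_og,
              dimnames = list(sprintf("OG%03d", seq_len(n_og)),
                              sprintf("G%02d", seq_len(n_genomes))))
  storage.mode(m) <- "integer"
  m
}

empty_features_for_test <- function() {
  data.frame(locus_tag = character(), contig = character(), start = integer(),
             end = integer(), strand = integer(), kind = character(),
             gene_name = character(), product = character(),
             protein_seq = character(), nucleotide_seq = character(),
             compound = logical(), stringsAsFactors = FALSE)
}

new_ogset_from_truth <- function(fx) {
  og <- fx$truth$orthogroups
  groups <- lapply(split(og[, c("genome_id", "locus_tag")], og$og_id),
                   function(d) { rownames(d) <- NULL; d })
  pangrove:::new_orthogroup_set(groups)
}

pipeline_store <- function() {
  cached("pipeline_store", function() {
    info <- fx_pipeline_dir()
    db <- file.path(tempdir(), "pangrove_store.sqlite")
    res <- run_pipeline(info$dir,
                        orthogroups = file.path(info$dir, "orthogroups.tsv"),
                        ko = file.path(info$dir, "ko.tsv"),
                        cog = file.path(info$dir, "cog.tsv"),
                        modules = file.path(info$dir, "modules.tsv"),
                        max_missing = 1, seed = 5, out_db = db)
    list(db = db, res = res, info = info)
  })
}

search_index_fixture <- function() {
  cached("search_index", function() {
    fx <- fx_small()
    ann <- data.frame(genome_id = fx$truth$ko$genome_id,
                      locus_tag = fx$truth$ko$locus_tag,
                      annotation_id = fx$truth$ko$ko,
                      stringsAsFactors = FALSE)
    build_search_index(fx$genomes, ann)
  })
}

fx_region_setup <- function() {
  cached("region_setup", function() {
    fx <- fx_small()
    ogset <- pangrove:::new_orthogroup_set(
      lapply(split(fx$truth$orthogroups[, c("genome_id", "locus_tag")],
                   fx$truth$orthogroups$og_id),
             function(d) { rownames(d) <- NULL; d }))
    list(fx = fx, ogset = ogset)
  })
}
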