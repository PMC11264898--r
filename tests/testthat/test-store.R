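test_that("a full run populates every table with resolvable foreign keys", {
  ps <- pipeline_store()
  tabs <- read_store(ps$db)
  for (nm in c("genomes", "contigs", "genes", "orthogroups", "gene_orthogroup",
               "annotations", "module_definitions", "completeness", "trees",
               "run_metadata"))
    expect_gt(nrow(tabs[[nm]]), 0)
  expect_true(all(tabs$genes$contig %in% tabs$contigs$accession))
  expect_true(all(tabs$gene_orthogroup$locus_tag %in% tabs$genes$locus_tag))
  expect_true(all(tabs$annotations$locus_tag %in% tabs$genes$locus_tag))
  expect_true(all(tabs$completeness$module_id %in% tabs$module_definitions$module_id))
  meta <- stats::setNames(tabs$run_metadata$value, tabs$run_metadata$key)
  expect_equal(meta[["schema_version"]], "1")
  expect_equal(meta[["has_tree"]], "TRUE")
  expect_equal(meta[["seed"]], "5")
})

test_that("a core-only run leaves optional tables empty and flags that in metadata", {
  info <- fx_pipeline_dir()
  db <- tempfile(fileext = ".sqlite")
  run_pipeline(info$dir, orthogroups = file.path(info$dir, "orthogroups.tsv"),
               max_missing = 1, out_db = db)
  tabs <- read_store(db)
  expect_equal(nrow(tabs$annotations), 0)
  expect_equal(nrow(tabs$completeness), 0)
  expect_gt(nrow(tabs$orthogroups), 0)
  meta <- stats::setNames(tabs$run_metadata$value, tabs$run_metadata$key)
  expect_equal(meta[["has_completeness"]], "FALSE")
  expect_equal(meta[["has_annotations"]], "FALSE")
})

test_that("rebuilding from identical inputs gives identical row sets", {
  ps <- pipeline_store()
  info <- ps$info
  db2 <- tempfile(fileext = ".sqlite")
  run_pipeline(info$dir,
               orthogroups = file.path(info$dir, "orthogroups.tsv"),
               ko = file.path(info$dir, "ko.tsv"),
               cog = file.path(info$dir, "cog.tsv"),
               modules = file.path(info$dir, "modules.tsv"),
               max_missing = 1, seed = 5, out_db = db2)
  expect_identical(read_store(ps$db), read_store(db2))
})

test_that("integrity violations abort naming the offending record", {
  fx <- fx_small()
  bad_og <- pangrove:::new_orthogroup_set(list(
    OGX = data.frame(genome_id = "GEN01", locus_tag = "GHOST_9999",
                     stringsAsFactors = FALSE)))
  expect_error(build_store(tempfile(), fx$genomes, bad_og), "GHOST_9999")
})

test_that("archive export/import round-trips every table and rejects corruption", {
  ps <- pipeline_store()
  ar <- tempfile(fileext = ".tar.gz")
  export_archive(ps$db, ar)
  db2 <- tempfile(fileext = ".sqlite")
  import_archive(ar, db2)
  expect_identical(read_store(ps$db), read_store(db2))

  # query results identical before export and after import
  for (db in c(ps$db, db2)) {
    tabs <- read_store(db)
    idx <- build_search_index(store_genomes(tabs))
    hits <- execute_query(parse_query("fam001 OR kind:pseudogene"), idx)
    if (db == ps$db) first_hits <- hits else expect_identical(hits, first_hits)
  }

  # truncation is caught
  raw <- readBin(ar, "raw", file.size(ar))
  short <- tempfile(fileext = ".tar.gz")
  writeBin(raw[seq_len(length(raw) %/% 2)], short)
  expect_error(import_archive(short, tempfile()), "corrupt|checksum")

  # newer schema version is refused
  stage <- tempfile(); dir.create(stage)
  utils::untar(ar, exdir = stage, tar = "internal")
  mf <- jsonlite::fromJSON(file.path(stage, "manifest.json"))
  mf$schema_version <- 999
  writeLines(jsonlite::toJSON(mf, auto_unbox = TRUE),
             file.path(stage, "manifest.json"))
  old <- setwd(stage)
  utils::tar("newer.tar.gz", files = c("manifest.json", "results.sqlite"),
             compression = "gzip", tar = "internal")
  setwd(old)
  expect_error(import_archive(file.path(stage, "newer.tar.gz"), tempfile()),
               "newer than supported")
})

test_that("the CLI drives the pipeline, stats, search and tree from the store alone", {
  info <- fx_pipeline_dir()
  db <- tempfile(fileext = ".sqlite")
  expect_message(
    cli_main(c("run", "--input", info$dir, "--out", db,
               "--orthogroups", file.path(info$dir, "orthogroups.tsv"),
               "--ko", file.path(info$dir, "ko.tsv"),
               "--modules", file.path(info$dir, "modules.tsv"),
               "--max-missing", "1", "--seed", "5")),
    "pipeline complete")

  spec_out <- capture.output(cli_main(c("stats", "--db", db, "--what", "spectrum")))
  expect_true(any(grepl("n_orthogroups", spec_out)))
  tree_out <- capture.output(cli_main(c("tree", "--db", db)))
  expect_true(any(grepl("^\\(", tree_out)))
  q_out <- capture.output(cli_main(c("query", "--db", db, "--expr", "fam001")))
  expect_gt(length(q_out), 1)
  mod_out <- capture.output(cli_main(c("modules", "--db", db)))
  expect_true(any(grepl("M00001", mod_out)))
  json_out <- paste(capture.output(
    cli_main(c("circos", "--db", db, "--reference", "GEN01",
               "--comparison", "GEN02,GEN03"))), collapse = "")
  expect_true(jsonlite::validate(json_out))
})

test_that("fixture generation is deterministic and honest about its bookkeeping", {
  cfg <- fixture_config(n_genomes = 3, n_families = 8, divergence = 0,
                        loss_rate = 0.2, seed = 902)
  fx1 <- generate_fixture(cfg)
  fx2 <- generate_fixture(cfg)
  expect_identical(fx1, fx2)

  # divergence 0: all family members identical; inference recovers the partition
  prote <- lapply(fx1$genomes, extract_sequences, alphabet = "protein")
  og <- infer_orthogroups(prote)
  planted <- split(fx1$truth$orthogroups$locus_tag, fx1$truth$orthogroups$og_id)
  expect_identical(canon_partition(lapply(og$groups, `[[`, "locus_tag")),
                   canon_partition(planted))

  # occupancy spectrum of the truth matches generator bookkeeping
  m <- fx1$truth$presence
  sp <- occupancy_spectrum(m)
  expect_equal(sum(sp), nrow(m))
  expect_equal(unname(sp[as.character(ncol(m))]),
               sum(rowSums(m >= 1) == ncol(m)))

  expect_error(fixture_config(seed = 1, divergence = 2), "rates")
  expect_error(fixture_config(n_genomes = 3), "seed is mandatory")

  # written files are byte-identical across runs of the same seed
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture(cfg, out_dir = d1)
  generate_fixture(cfg, out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})
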