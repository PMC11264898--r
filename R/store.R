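STORE_SCHEMA_VERSION <- 1L

store_table_names <- c("run_metadata", "genomes", "contigs", "genes",
                       "orthogroups", "gene_orthogroup", "identities",
                       "annotations", "module_definitions", "completeness",
                       "trees")

#' Build the result store
#'
#' Persists a full analysis run into a single-file SQLite database. The core
#' results (genomes, orthogroups) are required; optional analyses leave their
#' tables empty and are flagged in `run_metadata` so a consumer can tell
#' which analyses were performed. Referential integrity (genes to contigs
#' and genomes, orthogroup members to genes, annotations to genes,
#' completeness to module definitions) is verified before writing; a
#' violation aborts naming the offending records.
#'
#' @param path Output database file (overwritten).
#' @param genomes Named list of `genome_record`s.
#' @param ogset An `orthogroup_set`.
#' @param tree Optional [ape::phylo] species tree.
#' @param completeness Optional `completeness_matrix`.
#' @param module_definitions Optional named list of `module_definition`s.
#' @param annotations Optional data frame with columns `type`, `genome_id`,
#'   `locus_tag`, `key`, `value`, `provenance` (KO/COG/Pfam entries).
#' @param identities Optional data frame `locus_a`, `locus_b`, `identity`.
#' @param parameters Named list of run parameters (seeds, thresholds,
#'   n_orders, ...) recorded in `run_metadata`.
#' @return `path`, invisibly.
#' @export
build_store <- function(path, genomes, ogset, tree = NULL, completeness = NULL,
                        module_definitions = NULL, annotations = NULL,
                        identities = NULL, parameters = list()) {
  tabs <- assemble_store_tables(genomes, ogset, tree, completeness,
                                module_definitions, annotations, identities,
                                parameters)
  check_store_integrity(tabs)
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  for (nm in store_table_names)
    DBI::dbWriteTable(con, nm, tabs[[nm]], overwrite = TRUE)
  invisible(path)
}

assemble_store_tables <- function(genomes, ogset, tree, completeness,
                                  module_definitions, annotations, identities,
                                  parameters) {
  gtab <- data.frame(
    genome_id = vapply(genomes, `[[`, "", "genome_id"),
    display_name = vapply(genomes, `[[`, "", "display_name"),
    stringsAsFactors = FALSE)
  ctab <- do.call(rbind, lapply(genomes, function(g)
    data.frame(accession = vapply(g$contigs, `[[`, "", "accession"),
               genome_id = g$genome_id,
               length = vapply(g$contigs, `[[`, 0, "length"),
               sequence = vapply(g$contigs, `[[`, "", "sequence"),
               stringsAsFactors = FALSE)))
  genes <- do.call(rbind, lapply(genomes, function(g) {
    f <- g$features
    if (!nrow(f)) return(NULL)
    cbind(data.frame(genome_id = g$genome_id, stringsAsFactors = FALSE),
          f[, c("locus_tag", "contig", "start", "end", "strand", "kind",
                "gene_name", "product", "protein_seq", "nucleotide_seq")])
  }))
  rownames(genes) <- rownames(ctab) <- rownames(gtab) <- NULL

  og_sizes <- vapply(ogset$groups, nrow, 0L)
  ogtab <- data.frame(og_id = names(ogset$groups), n_genes = og_sizes,
                      stringsAsFactors = FALSE)
  gog <- do.call(rbind, lapply(names(ogset$groups), function(og)
    cbind(data.frame(og_id = og, stringsAsFactors = FALSE),
          ogset$groups[[og]])))
  rownames(ogtab) <- rownames(gog) <- NULL

  comp <- data.frame(module_id = character(), genome_id = character(),
                     completeness = numeric(), used_propagated = logical(),
                     stringsAsFactors = FALSE)
  moddef <- data.frame(module_id = character(), definition = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(completeness)) {
    cm <- completeness$completeness
    comp <- do.call(rbind, lapply(rownames(cm), function(m)
      data.frame(module_id = m, genome_id = colnames(cm),
                 completeness = cm[m, ],
                 used_propagated = vapply(colnames(cm), function(g)
                   isTRUE(completeness$results[[m]][[g]]$used_propagated), TRUE),
                 stringsAsFactors = FALSE)))
    rownames(comp) <- NULL
  }
  if (!is.null(module_definitions))
    moddef <- data.frame(
      module_id = names(module_definitions),
      definition = vapply(module_definitions, serialize_module_definition, ""),
      stringsAsFactors = FALSE)

  ann <- if (is.null(annotations))
    data.frame(type = character(), genome_id = character(),
               locus_tag = character(), key = character(), value = character(),
               provenance = character(), stringsAsFactors = FALSE)
  else annotations

  idtab <- if (is.null(identities))
    data.frame(locus_a = character(), locus_b = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  else identities

  trees <- if (is.null(tree))
    data.frame(name = character(), newick = character(), stringsAsFactors = FALSE)
  else data.frame(name = "species_tree", newick = ape::write.tree(tree),
                  stringsAsFactors = FALSE)

  meta <- data.frame(
    key = c("schema_version", "tool_version",
            "has_tree", "has_completeness", "has_annotations",
            names(parameters)),
    value = c(as.character(STORE_SCHEMA_VERSION),
              as.character(utils::packageVersion("pangrove")),
              as.character(!is.null(tree)), as.character(!is.null(completeness)),
              as.character(!is.null(annotations) && nrow(ann) > 0),
              vapply(parameters, function(p) paste(as.character(p), collapse = ","), "")),
    stringsAsFactors = FALSE)

  list(run_metadata = meta, genomes = gtab, contigs = ctab, genes = genes,
       orthogroups = ogtab, gene_orthogroup = gog, identities = idtab,
       annotations = ann, module_definitions = moddef, completeness = comp,
       trees = trees)
}

check_store_integrity <- function(tabs) {
  fail <- function(what, bad)
    stop("store integrity violation: ", what, ": ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!nrow(tabs$genomes)) stop("store requires at least one genome")
  bad <- setdiff(tabs$contigs$genome_id, tabs$genomes$genome_id)
  if (length(bad)) fail("contigs referencing unknown genome", bad)
  bad <- setdiff(tabs$genes$contig, tabs$contigs$accession)
  if (length(bad)) fail("genes referencing unknown contig", bad)
  bad <- setdiff(tabs$gene_orthogroup$locus_tag, tabs$genes$locus_tag)
  if (length(bad)) fail("orthogroup members referencing unknown gene", bad)
  bad <- setdiff(tabs$gene_orthogroup$og_id, tabs$orthogroups$og_id)
  if (length(bad)) fail("orthogroup membership for unknown orthogroup", bad)
  if (nrow(tabs$annotations)) {
    bad <- setdiff(tabs$annotations$locus_tag, tabs$genes$locus_tag)
    if (length(bad)) fail("annotations referencing unknown gene", bad)
  }
  if (nrow(tabs$completeness)) {
    bad <- setdiff(tabs$completeness$module_id, tabs$module_definitions$module_id)
    if (length(bad)) fail("completeness for unknown module", bad)
    bad <- setdiff(tabs$completeness$genome_id, tabs$genomes$genome_id)
    if (length(bad)) fail("completeness for unknown genome", bad)
  }
  invisible(TRUE)
}

#' Read every table of a result store
#'
#' @param path Store database file.
#' @return Named list of data frames, one per table.
#' @export
read_store <- function(path) {
  if (!file.exists(path)) stop("store not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  out <- lapply(stats::setNames(store_table_names, store_table_names),
                function(nm) DBI::dbReadTable(con, nm))
  out
}

#' Reconstruct genome records from a store
#'
#' Inverse of the genome tables written by [build_store()]; used by the CLI
#' region/circos subcommands so plots can be produced from the database
#' alone.
#'
#' @param tabs Table list from [read_store()].
#' @return Named list of `genome_record` objects.
#' @export
store_genomes <- function(tabs) {
  out <- list()
  for (i in seq_len(nrow(tabs$genomes))) {
    gid <- tabs$genomes$genome_id[i]
    ct <- tabs$contigs[tabs$contigs$genome_id == gid, , drop = FALSE]
    contigs <- stats::setNames(lapply(seq_len(nrow(ct)), function(j)
      list(accession = ct$accession[j], sequence = ct$sequence[j],
           length = ct$length[j])), ct$accession)
    f <- tabs$genes[tabs$genes$genome_id == gid, , drop = FALSE]
    f <- f[, c("locus_tag", "contig", "start", "end", "strand", "kind",
               "gene_name", "product", "protein_seq", "nucleotide_seq")]
    f$compound <- FALSE
    rownames(f) <- NULL
    out[[gid]] <- structure(
      list(genome_id = gid, display_name = tabs$genomes$display_name[i],
           contigs = contigs, features = f),
      class = "genome_record")
  }
  out
}

#' Rebuild the orthogroup set from a store
#'
#' @param tabs Table list from [read_store()].
#' @return An `orthogroup_set`.
#' @export
store_ogset <- function(tabs) {
  groups <- split(tabs$gene_orthogroup[, c("genome_id", "locus_tag")],
                  tabs$gene_orthogroup$og_id)
  groups <- lapply(groups, function(d) { rownames(d) <- NULL; d })
  new_orthogroup_set(groups[tabs$orthogroups$og_id])
}

#' Export a result store as a portable archive
#'
#' Produces a gzip-compressed tar holding the database file and a JSON
#' manifest (schema version, tool version, md5 checksum of the database).
#'
#' @param store_path Store database file.
#' @param archive_path Output archive (`.tar.gz`).
#' @return `archive_path`, invisibly.
#' @export
export_archive <- function(store_path, archive_path) {
  if (!file.exists(store_path)) stop("store not found: ", store_path)
  stage <- tempfile("archive_stage")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  file.copy(store_path, file.path(stage, "results.sqlite"))
  manifest <- list(schema_version = STORE_SCHEMA_VERSION,
                   tool_version = as.character(utils::packageVersion("pangrove")),
                   md5 = unname(tools::md5sum(file.path(stage, "results.sqlite"))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             file.path(stage, "manifest.json"))
  old <- getwd()
  dest <- if (grepl("^/", archive_path)) archive_path
          else file.path(old, archive_path)
  setwd(stage)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(dest, files = c("manifest.json", "results.sqlite"),
             compression = "gzip", tar = "internal")
  invisible(archive_path)
}

#' Import a result store from an archive
#'
#' Unpacks the archive, verifies the manifest checksum and schema
#' compatibility, and installs the database at `store_path`. A corrupted
#' archive or one written by a newer schema is refused without partial
#' import.
#'
#' @param archive_path Archive produced by [export_archive()].
#' @param store_path Destination database file.
#' @return `store_path`, invisibly.
#' @export
import_archive <- function(archive_path, store_path) {
  if (!file.exists(archive_path)) stop("archive not found: ", archive_path)
  stage <- tempfile("archive_unpack")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  ok <- tryCatch({
    utils::untar(archive_path, exdir = stage, tar = "internal")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    # the internal untar can leave its output connection open on failure
    cons <- showConnections(all = FALSE)
    stale <- which(startsWith(cons[, "description"], stage) |
                     basename(cons[, "description"]) %in%
                       c("results.sqlite", "manifest.json"))
    for (i in rev(stale)) try(close(getConnection(as.integer(rownames(cons)[i]))),
                              silent = TRUE)
  }
  mf <- file.path(stage, "manifest.json")
  db <- file.path(stage, "results.sqlite")
  if (!ok || !file.exists(mf) || !file.exists(db))
    stop("archive is corrupt or incomplete: ", archive_path)
  manifest <- jsonlite::fromJSON(mf)
  if (is.null(manifest$md5) || !identical(unname(tools::md5sum(db)), manifest$md5))
    stop("archive checksum mismatch: ", archive_path)
  if (as.integer(manifest$schema_version) > STORE_SCHEMA_VERSION)
    stop("archive schema version ", manifest$schema_version,
         " is newer than supported version ", STORE_SCHEMA_VERSION,
         "; refusing import")
  file.copy(db, store_path, overwrite = TRUE)
  invisible(store_path)
}
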