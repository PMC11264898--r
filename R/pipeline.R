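#' Run the full analysis pipeline
#'
#' From annotated genomes to a populated result store: parse GenBank files,
#' enforce identifier uniqueness, obtain orthogroups (from a supplied table
#' or via built-in reciprocal-best-hit inference), compute the presence
#' matrix and conservation statistics, select the relaxed single-copy core
#' and build the concatenated-alignment neighbor-joining species tree, and,
#' when KO/COG annotation tables and module definitions are supplied,
#' propagate KO annotations through orthogroups and score module
#' completeness. All results are optionally persisted with [build_store()].
#'
#' @param input Either a directory containing `.gbk`/`.gbff` files or a named
#'   list of `genome_record`s.
#' @param orthogroups Optional path to an orthogroup TSV
#'   ([read_orthogroup_table()] dialect); when NULL, orthology is inferred
#'   with [infer_orthogroups()].
#' @param ko,cog,modules Optional paths to KO assignment, COG annotation and
#'   module definition TSVs.
#' @param max_missing Relaxation of the single-copy core (default 0).
#' @param seed Seed recorded in metadata and used for accumulation curves.
#' @param n_orders Orderings averaged in the accumulation curves.
#' @param min_identity,min_coverage Thresholds for the built-in orthology
#'   inference.
#' @param aligner Passed to [align_core_families()].
#' @param out_db Optional path; when given the result store is written there.
#' @param skip_tree Skip core selection and tree building (e.g. data sets
#'   with no shared single-copy core).
#' @return List with `genomes`, `renames`, `ogset`, `matrix`, `spectrum`,
#'   `curves`, `core`, `tree`, `assignments`, `completeness`, `cog_profile`,
#'   `summaries`, `parameters`.
#' @export
run_pipeline <- function(input, orthogroups = NULL, ko = NULL, cog = NULL,
                         modules = NULL, max_missing = 0, seed = 42,
                         n_orders = 100, min_identity = 30, min_coverage = 0.5,
                         aligner = "identity", out_db = NULL,
                         skip_tree = FALSE) {
  genomes <- if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.(gbk|gbff|gb|genbank)$",
                             full.names = TRUE))
    if (!length(files)) stop("no GenBank files found in ", input)
    lapply(files, parse_genbank)
  } else input
  san <- sanitize_identifiers(unname(genomes))
  genomes <- san$genomes
  names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  gids <- names(genomes)

  proteomes <- lapply(genomes, extract_sequences, alphabet = "protein")
  ogset <- if (!is.null(orthogroups))
    read_orthogroup_table(orthogroups, genomes)
  else infer_orthogroups(proteomes, min_identity = min_identity,
                         min_coverage = min_coverage)

  mat <- presence_matrix(ogset, gids)
  spectrum <- occupancy_spectrum(mat)
  curves <- accumulation_curves(mat, n_orders = n_orders, seed = seed)

  core <- NULL; tree <- NULL
  if (!skip_tree && length(gids) >= 3) {
    core <- select_core_orthologs(mat, max_missing = max_missing)
    alns <- align_core_families(ogset, proteomes, core, aligner = aligner)
    super <- concatenate_alignments(alns, core, gids)
    dm <- distance_matrix(super)
    tree <- nj_tree(dm)
  }

  assignments <- NULL; comp <- NULL; defs <- NULL
  if (!is.null(ko)) {
    assignments <- propagate_annotations(read_ko_assignments(ko), ogset,
                                         genomes = genomes)
    if (!is.null(modules)) {
      defs <- read_module_definitions(modules)
      comp <- completeness_matrix(defs, assignments, gids,
                                  use_propagated = TRUE)
    }
  }
  cog_profile <- NULL
  cog_tab <- NULL
  if (!is.null(cog)) {
    cog_tab <- read_category_annotations(cog)
    gene_counts <- vapply(genomes, function(g) nrow(g$features), 0L)
    cog_profile <- category_distribution(cog_tab, gene_counts,
                                         normalize = "proportion_of_genes")
  }

  params <- list(seed = seed, n_orders = n_orders, max_missing = max_missing,
                 min_identity = min_identity, min_coverage = min_coverage,
                 aligner = aligner,
                 orthology_source = if (is.null(orthogroups)) "builtin_rbh"
                                    else "table")
  if (!is.null(out_db)) {
    ann <- store_annotation_table(assignments, cog_tab)
    build_store(out_db, genomes, ogset, tree = tree, completeness = comp,
                module_definitions = defs, annotations = ann,
                parameters = params)
  }
  list(genomes = genomes, renames = san$renames, ogset = ogset, matrix = mat,
       spectrum = spectrum, curves = curves, core = core, tree = tree,
       assignments = assignments, completeness = comp,
       cog_profile = cog_profile, summaries = genome_summary_table(genomes),
       parameters = params)
}

store_annotation_table <- function(assignments, cog_tab) {
  rows <- list()
  if (!is.null(assignments) && nrow(assignments))
    rows[[1]] <- data.frame(type = "KO", genome_id = assignments$genome_id,
                            locus_tag = assignments$locus_tag, key = assignments$ko,
                            value = NA_character_,
                            provenance = assignments$provenance,
                            stringsAsFactors = FALSE)
  if (!is.null(cog_tab) && nrow(cog_tab))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "COG", genome_id = cog_tab$genome_id,
      locus_tag = cog_tab$locus_tag, key = cog_tab$annotation_id,
      value = cog_tab$category_code, provenance = "direct",
      stringsAsFactors = FALSE)
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
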