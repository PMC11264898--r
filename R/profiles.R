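#' Per-genome distribution of functional categories
#'
#' Aggregates COG- or KEGG-style category annotations into a category-by-
#' genome matrix. A gene carrying several categories contributes once to each
#' of them (so count columns may sum above the number of annotated genes; the
#' convention is recorded in the output attributes). In proportion mode the
#' denominator is the total number of genes in the genome and an explicit
#' `unannotated` row accounts for genes with no category, so that distinct
#' annotated genes plus unannotated genes cover every gene exactly once.
#'
#' @param annotations Data frame with columns `genome_id`, `locus_tag`,
#'   `category_code` (one row per gene-category pair) and optionally
#'   `category_label`.
#' @param gene_counts Named integer vector: total genes per genome; names are
#'   the genome ids and define the matrix columns.
#' @param normalize `"counts"` or `"proportion_of_genes"`.
#' @return Numeric matrix category x genome; in proportion mode the last row
#'   is `unannotated`. Attribute `multi_category` documents the counting
#'   convention.
#' @export
category_distribution <- function(annotations, gene_counts,
                                  normalize = c("counts", "proportion_of_genes")) {
  normalize <- match.arg(normalize)
  genome_ids <- names(gene_counts)
  if (is.null(genome_ids)) stop("gene_counts must be named by genome id")
  unknown <- setdiff(unique(annotations$genome_id), genome_ids)
  if (length(unknown))
    stop("annotations reference unknown genome(s): ",
         paste(unknown, collapse = ", "))

  ann <- unique(annotations[, c("genome_id", "locus_tag", "category_code")])
  cats <- sort(unique(ann$category_code))
  m <- matrix(0, nrow = length(cats), ncol = length(genome_ids),
              dimnames = list(cats, genome_ids))
  if (nrow(ann)) {
    tab <- table(ann$category_code, ann$genome_id)
    m[rownames(tab), colnames(tab)] <- as.numeric(tab)
  }
  if (normalize == "proportion_of_genes") {
    annotated <- vapply(genome_ids, function(g)
      length(unique(ann$locus_tag[ann$genome_id == g])), 0L)
    if (any(annotated > gene_counts[genome_ids]))
      stop("more annotated genes than total genes for some genome")
    unann <- gene_counts[genome_ids] - annotated
    m <- rbind(m, unannotated = unann)
    m <- sweep(m, 2, gene_counts[genome_ids], "/")
  }
  attr(m, "multi_category") <-
    "genes with several categories are counted once per category"
  attr(m, "normalize") <- normalize
  m
}

#' Read a category annotation TSV
#'
#' @param path TSV with columns `genome_id`, `locus_tag`, `annotation_id`,
#'   `category_code`, `category_label` (header auto-detected).
#' @return Data frame with those columns.
#' @export
read_category_annotations <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("genome_id", "locus_tag",
                                         "annotation_id", "category_code",
                                         "category_label"))
  if (nrow(tab) && tab$genome_id[1] == "genome_id") tab <- tab[-1, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
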