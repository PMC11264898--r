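#' Read an orthogroup assignment table
#'
#' Ingests the tab-separated orthogroup format produced by standard orthology
#' tools ("Orthogroups.tsv" dialect): first column the orthogroup id, one
#' column per genome, cells holding comma(+space)-separated locus tags. Genes
#' present in the genomes but absent from the table are appended as singleton
#' groups; the returned object records that policy in `unassigned_policy`.
#'
#' @param path Path to the TSV file.
#' @param genomes List of parsed `genome_record` objects; every referenced
#'   locus tag must exist in them.
#' @return An `orthogroup_set`: list with `groups` (named list og_id ->
#'   data frame `genome_id`, `locus_tag`) and `unassigned_policy`.
#' @export
read_orthogroup_table <- function(path, genomes) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("orthogroup table needs an id column plus genome columns")
  genome_ids <- vapply(genomes, `[[`, "", "genome_id")
  cols <- colnames(tab)[-1]
  unknown <- setdiff(cols, genome_ids)
  if (length(unknown))
    stop("unknown genome column(s) in orthogroup table: ",
         paste(unknown, collapse = ", "))

  gene_index <- gene_universe(genomes)
  groups <- list()
  seen <- character(0)
  for (i in seq_len(nrow(tab))) {
    og <- as.character(tab[i, 1])
    members <- list()
    for (g in cols) {
      cell <- tab[i, g]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      tags <- trimws(strsplit(cell, ",")[[1]])
      tags <- tags[nzchar(tags)]
      if (length(tags))
        members[[length(members) + 1L]] <-
          data.frame(genome_id = g, locus_tag = tags, stringsAsFactors = FALSE)
    }
    if (!length(members)) next
    mem <- do.call(rbind, members)
    dupes <- intersect(mem$locus_tag, seen)
    if (length(dupes))
      stop("locus tag(s) assigned to more than one orthogroup: ",
           paste(dupes, collapse = ", "))
    missing <- setdiff(mem$locus_tag, gene_index$locus_tag)
    if (length(missing))
      stop("orthogroup table references unknown locus tag(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    seen <- c(seen, mem$locus_tag)
    groups[[og]] <- mem
  }
  # genes not covered by the table become singletons
  orphan <- gene_index[!(gene_index$locus_tag %in% seen) &
                         gene_index$kind == "CDS", , drop = FALSE]
  policy <- if (nrow(orphan)) "unassigned_as_singletons" else "all_assigned"
  for (i in seq_len(nrow(orphan))) {
    og <- sprintf("OG_single_%s", orphan$locus_tag[i])
    groups[[og]] <- data.frame(genome_id = orphan$genome_id[i],
                               locus_tag = orphan$locus_tag[i],
                               stringsAsFactors = FALSE)
  }
  new_orthogroup_set(groups, policy)
}

new_orthogroup_set <- function(groups, policy = "all_assigned") {
  structure(list(groups = groups, unassigned_policy = policy),
            class = "orthogroup_set")
}

#' @export
print.orthogroup_set <- function(x, ...) {
  sizes <- vapply(x$groups, nrow, 0L)
  cat(sprintf("<orthogroup_set> %d groups, %d genes (%d singletons)\n",
              length(x$groups), sum(sizes), sum(sizes == 1L)))
  invisible(x)
}

gene_universe <- function(genomes) {
  do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g$features)) return(NULL)
    data.frame(genome_id = g$genome_id, locus_tag = g$features$locus_tag,
               kind = g$features$kind, stringsAsFactors = FALSE)
  }))
}

#' Infer orthogroups by reciprocal best hits
#'
#' A test-scale orthology inference intended for small data sets: all
#' inter-genome protein pairs are aligned locally (BLOSUM62, gap open 11,
#' gap extend 1); for each ordered genome pair the best hit per query passing
#' the identity and coverage thresholds is retained (ties broken by
#' lexicographic locus tag, so the result is deterministic and independent of
#' genome input order); reciprocal best-hit pairs form the edges of a graph
#' whose connected components are the orthogroups. Genes with no edge become
#' singletons. A full-scale orthology tool's output can be substituted via
#' [read_orthogroup_table()].
#'
#' @param proteomes Named list (genome_id -> [Biostrings::AAStringSet] named
#'   by locus tag), e.g. from [extract_sequences()].
#' @param min_identity Minimum percent identity of the local alignment
#'   (default 30).
#' @param min_coverage Minimum fraction of the shorter sequence covered by
#'   the alignment (default 0.5).
#' @return An `orthogroup_set`.
#' @export
infer_orthogroups <- function(proteomes, min_identity = 30, min_coverage = 0.5) {
  if (length(proteomes) < 2) stop("need at least two genomes")
  if (min_identity < 0 || min_identity > 100) stop("min_identity must be in [0,100]")
  if (min_coverage < 0 || min_coverage > 1) stop("min_coverage must be in [0,1]")
  gids <- sort(names(proteomes))
  blosum <- get_blosum62()

  best <- list()  # "qgenome|sgenome" -> named character: query tag -> best subject tag
  for (qa in gids) for (sb in gids) {
    if (qa == sb) next
    q <- proteomes[[qa]]; s <- proteomes[[sb]]
    if (!length(q) || !length(s)) next
    hits <- character(0)
    for (qi in seq_along(q)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = s, subject = q[[qi]], type = "local",
        substitutionMatrix = blosum, gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(aln)
      nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
      cols <- nm + nmm
      ident <- ifelse(cols > 0, 100 * nm / cols, 0)
      shorter <- pmin(Biostrings::width(s), length(q[[qi]]))
      cover <- cols / shorter
      ok <- which(ident >= min_identity & cover >= min_coverage & sc > 0)
      if (!length(ok)) next
      ord <- ok[order(-sc[ok], names(s)[ok])]
      hits[[names(q)[qi]]] <- names(s)[ord[1]]
    }
    best[[paste(qa, sb, sep = "|")]] <- hits
  }

  edges <- character(0)
  for (qa in gids) for (sb in gids) {
    if (qa >= sb) next
    fwd <- best[[paste(qa, sb, sep = "|")]]
    rev <- best[[paste(sb, qa, sep = "|")]]
    for (qt in names(fwd)) {
      st <- fwd[[qt]]
      if (!is.null(rev[[st]]) && rev[[st]] == qt)
        edges <- c(edges, qt, st)
    }
  }

  tag2genome <- unlist(lapply(gids, function(g)
    stats::setNames(rep(g, length(proteomes[[g]])), names(proteomes[[g]]))))
  all_tags <- names(tag2genome)
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(all_tags)
  if (length(edges)) gr <- gr + igraph::edges(edges)
  comp <- igraph::components(gr)
  membership <- comp$membership
  groups <- split(names(membership), membership)
  # order-invariant ids: sort components by their smallest locus tag
  key <- vapply(groups, function(m) min(m), "")
  groups <- groups[order(key)]
  out <- list()
  for (i in seq_along(groups)) {
    m <- sort(groups[[i]])
    out[[sprintf("OG%07d", i)]] <-
      data.frame(genome_id = unname(tag2genome[m]), locus_tag = m,
                 stringsAsFactors = FALSE)
  }
  new_orthogroup_set(out)
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Orthogroup-by-genome copy-number matrix
#'
#' @param ogset An `orthogroup_set`.
#' @param genome_ids Character vector of genome ids (matrix columns, in this
#'   order).
#' @return Integer matrix, rows = orthogroup ids, columns = genome ids,
#'   cells = copy number of the group in the genome. Cells above 1 mark
#'   multi-copy (paralogous) groups.
#' @export
presence_matrix <- function(ogset, genome_ids) {
  ogs <- names(ogset$groups)
  m <- matrix(0L, nrow = length(ogs), ncol = length(genome_ids),
              dimnames = list(ogs, genome_ids))
  for (og in ogs) {
    tab <- table(ogset$groups[[og]]$genome_id)
    bad <- setdiff(names(tab), genome_ids)
    if (length(bad))
      stop("orthogroup ", og, " references genome(s) not in the genome list: ",
           paste(bad, collapse = ", "))
    m[og, names(tab)] <- as.integer(tab)
  }
  m
}

#' Percent amino-acid identity of two proteins
#'
#' Global (Needleman-Wunsch) alignment under BLOSUM62 with gap open 11 and
#' gap extend 1; identity is 100 times the number of identical residue pairs
#' divided by the number of aligned columns where neither side is a gap.
#' Symmetric and bounded in \[0, 100\]; a pair with no ungapped aligned
#' column scores 0.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings (or `AAString`).
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = get_blosum62(), gapOpening = 11, gapExtension = 1)
  nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
  if (nm + nmm == 0) return(0)
  100 * nm / (nm + nmm)
}
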