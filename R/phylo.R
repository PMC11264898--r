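#' Select relaxed single-copy core orthogroups
#'
#' The species tree is built from orthogroups that are single copy wherever
#' present. Because draft assemblies may miss genes, the requirement of
#' presence in all G genomes can be relaxed: a group qualifies when it has
#' copy number exactly 1 in at least `G - max_missing` genomes, copy number 0
#' elsewhere, and no genome with 2+ copies (paralogous groups are excluded
#' regardless of `max_missing`).
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @param max_missing Number of genomes allowed to lack a core group
#'   (default 0; must be < G).
#' @return A `core_selection`: list with `og_ids` (sorted), `max_missing` and
#'   `coverage` (named vector: genomes carrying each selected group).
#' @export
select_core_orthologs <- function(matrix, max_missing = 0) {
  G <- ncol(matrix)
  if (max_missing < 0 || max_missing >= G)
    stop("max_missing must satisfy 0 <= max_missing < number of genomes")
  single <- rowSums(matrix == 1)
  multi <- rowSums(matrix >= 2)
  zero <- rowSums(matrix == 0)
  sel <- multi == 0 & single >= G - max_missing & single + zero == G
  ogs <- sort(rownames(matrix)[sel])
  if (!length(ogs))
    stop("no single-copy core orthogroups at max_missing = ", max_missing,
         "; consider a larger max_missing")
  structure(list(og_ids = ogs, max_missing = max_missing,
                 coverage = stats::setNames(single[ogs], ogs)),
            class = "core_selection")
}

#' Concatenate per-orthogroup alignments into a super-alignment
#'
#' Rows are genomes; each selected orthogroup contributes one partition of
#' columns. A genome missing from an orthogroup receives all-gap columns for
#' that partition. All rows of each input alignment must have equal length.
#'
#' @param alignments Named list (og_id -> named character vector or
#'   [Biostrings::AAStringSet] of aligned, equal-length sequences keyed by
#'   genome id).
#' @param selection A `core_selection`; its `og_ids` choose and order the
#'   partitions.
#' @param genome_ids Character vector of genome ids (row set, in order).
#' @return A `super_alignment`: list with `rows` (named character vector,
#'   one gapped sequence per genome) and `partitions` (data frame `og_id`,
#'   `start`, `end`, 1-based inclusive column ranges).
#' @export
concatenate_alignments <- function(alignments, selection, genome_ids) {
  ogs <- selection$og_ids
  missing_aln <- setdiff(ogs, names(alignments))
  if (length(missing_aln))
    stop("no alignment supplied for orthogroup(s): ",
         paste(missing_aln, collapse = ", "))
  rows <- stats::setNames(rep("", length(genome_ids)), genome_ids)
  parts <- list()
  pos <- 0L
  for (og in ogs) {
    aln <- alignments[[og]]
    aln <- stats::setNames(as.character(aln), names(aln))
    w <- unique(nchar(aln))
    if (length(w) != 1L)
      stop("ragged alignment for orthogroup ", og,
           " (row lengths ", paste(w, collapse = ", "), ")")
    gaprow <- strrep("-", w)
    for (g in genome_ids)
      rows[[g]] <- paste0(rows[[g]], if (g %in% names(aln)) aln[[g]] else gaprow)
    parts[[length(parts) + 1L]] <-
      data.frame(og_id = og, start = pos + 1L, end = pos + w,
                 stringsAsFactors = FALSE)
    pos <- pos + w
  }
  structure(list(rows = rows, partitions = do.call(rbind, parts)),
            class = "super_alignment")
}

#' Pairwise-deletion identity distances from a super-alignment
#'
#' d(a, b) = 1 - (fraction of identical residues over the columns where
#' neither row has a gap). Comparable columns are determined per pair
#' (pairwise deletion), not globally.
#'
#' @param alignment A `super_alignment` (or named character vector of
#'   equal-length gapped sequences).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment) {
  rows <- if (inherits(alignment, "super_alignment")) alignment$rows else alignment
  if (length(rows) < 2) stop("need at least two rows")
  if (length(unique(nchar(rows))) != 1) stop("rows differ in length")
  ids <- names(rows)
  chars <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(chars) <- ids
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns between ", ids[i], " and ", ids[j])
    d[i, j] <- d[j, i] <- 1 - mean(chars[i, ok] == chars[j, ok])
  }
  d
}

#' Neighbor-joining species tree
#'
#' Classical neighbor-joining on a symmetric distance matrix. Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero
#' with the deficit moved to the sister branch so that path lengths are
#' preserved as far as possible. With exactly two taxa a trivial single-edge
#' tree is returned.
#'
#' @param distances Symmetric numeric matrix with taxon names.
#' @return An [ape::phylo] tree (unrooted, branch lengths >= 0).
#' @export
nj_tree <- function(distances) {
  n <- nrow(distances)
  if (n < 2) stop("need at least two taxa")
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(distances)[1], distances[1, 2] / 2,
                                        rownames(distances)[2], distances[1, 2] / 2))
    return(tr)
  }
  # stable taxon order for deterministic tie handling
  ord <- order(rownames(distances))
  d <- distances[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

# negative edge -> 0; deficit added to the sister edge (same parent node)
clamp_negative_branches <- function(tree) {
  for (iter in seq_len(10L * nrow(tree$edge))) {
    neg <- which(tree$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (!length(sibs)) break
    tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Leaf-to-leaf path lengths of a tree
#'
#' Sums branch lengths along the unique path between every pair of leaves.
#' For a tree built from additive distances this reproduces the input matrix.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric numeric matrix over the tip labels.
#' @export
tree_path_lengths <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  out <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(nt)) {
    dist <- rep(NA_real_, nn)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        u <- nb[k, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + nb[k, 2]
          queue <- c(queue, u)
        }
      }
    }
    out[s, ] <- dist[seq_len(nt)]
  }
  out
}

#' Align the members of selected orthogroups
#'
#' Per-orthogroup protein alignments for the concatenation step. The
#' `"identity"` aligner requires all members of a group to have equal length
#' (true of families that diverged by substitution only, as produced by the
#' fixture generator) and returns them unchanged; `"mafft"` shells out to a
#' mafft executable on the PATH for genuinely gapped alignments.
#'
#' @param ogset An `orthogroup_set`.
#' @param proteomes Named list (genome_id -> named [Biostrings::AAStringSet]).
#' @param selection A `core_selection` naming the groups to align.
#' @param aligner `"identity"` or `"mafft"`.
#' @return Named list og_id -> named character vector (genome_id -> aligned
#'   sequence), suitable for [concatenate_alignments()].
#' @export
align_core_families <- function(ogset, proteomes, selection,
                                aligner = c("identity", "mafft")) {
  aligner <- match.arg(aligner)
  out <- list()
  for (og in selection$og_ids) {
    mem <- ogset$groups[[og]]
    seqs <- stats::setNames(vapply(seq_len(nrow(mem)), function(i)
      as.character(proteomes[[mem$genome_id[i]]][[mem$locus_tag[i]]]), ""),
      mem$genome_id)
    if (aligner == "identity") {
      if (length(unique(nchar(seqs))) != 1)
        stop("orthogroup ", og, " members differ in length; use aligner = \"mafft\"")
      out[[og]] <- seqs
    } else {
      out[[og]] <- run_mafft(seqs)
    }
  }
  out
}

run_mafft <- function(seqs) {
  exe <- Sys.which("mafft")
  if (!nzchar(exe)) stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".aln")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fin)
  system2(exe, c("--quiet", "--auto", fin), stdout = fout)
  aln <- Biostrings::readAAStringSet(fout)
  stats::setNames(as.character(aln), names(aln))
}
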