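#' Enforce identifier uniqueness across a set of genomes
#'
#' Locally assembled genomes frequently reuse locus tags or contig accessions.
#' This scans all genomes in input order and renames any repeated locus tag or
#' contig accession by appending `_dupN`, with `N` the smallest positive
#' integer that avoids a further collision. The operation is deterministic for
#' a fixed input ordering and idempotent: running it on already-unique input
#' returns the input unchanged with an empty rename map.
#'
#' @param genomes List of `genome_record` objects.
#' @return List with `genomes` (renamed records, same order) and `renames`,
#'   a data frame with columns `kind` ("locus_tag" or "contig"), `genome_id`,
#'   `old`, `new` recording every change.
#' @export
sanitize_identifiers <- function(genomes) {
  stopifnot(length(genomes) >= 1)
  seen_tags <- character(0)
  seen_contigs <- character(0)
  renames <- list()
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    # contig accessions
    for (ci in seq_along(g$contigs)) {
      acc <- g$contigs[[ci]]$accession
      new <- dedup_name(acc, seen_contigs)
      if (new != acc) {
        g$features$contig[g$features$contig == acc] <- new
        g$contigs[[ci]]$accession <- new
        renames[[length(renames) + 1L]] <- data.frame(
          kind = "contig", genome_id = g$genome_id, old = acc, new = new,
          stringsAsFactors = FALSE)
      }
      seen_contigs <- c(seen_contigs, new)
    }
    names(g$contigs) <- vapply(g$contigs, `[[`, "", "accession")
    # locus tags
    if (nrow(g$features)) for (fi in seq_len(nrow(g$features))) {
      tag <- g$features$locus_tag[fi]
      new <- dedup_name(tag, seen_tags)
      if (new != tag) {
        g$features$locus_tag[fi] <- new
        renames[[length(renames) + 1L]] <- data.frame(
          kind = "locus_tag", genome_id = g$genome_id, old = tag, new = new,
          stringsAsFactors = FALSE)
      }
      seen_tags <- c(seen_tags, new)
    }
    genomes[[gi]] <- g
  }
  map <- if (length(renames)) do.call(rbind, renames) else
    data.frame(kind = character(), genome_id = character(),
               old = character(), new = character(), stringsAsFactors = FALSE)
  list(genomes = genomes, renames = map)
}

dedup_name <- function(name, seen) {
  if (!(name %in% seen)) return(name)
  n <- 1L
  repeat {
    cand <- sprintf("%s_dup%d", name, n)
    if (!(cand %in% seen)) return(cand)
    n <- n + 1L
  }
}

#' Extract protein or nucleotide sequences from a genome
#'
#' Protein mode returns one record per CDS (pseudogenes excluded, as they
#' carry no product); nucleotide mode returns one record per gene feature,
#' pseudogenes included. Record names are locus tags; order follows genomic
#' coordinates (contig, then start).
#'
#' @param genome A `genome_record`.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return An [Biostrings::AAStringSet] (protein) or
#'   [Biostrings::DNAStringSet] (nucleotide) named by locus tag.
#' @export
extract_sequences <- function(genome, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  fs <- genome$features
  ord <- order(match(fs$contig, names(genome$contigs)), fs$start)
  fs <- fs[ord, , drop = FALSE]
  if (alphabet == "protein") {
    fs <- fs[fs$kind == "CDS" & !is.na(fs$protein_seq), , drop = FALSE]
    if (!nrow(fs)) {
      warning("genome ", genome$genome_id, " has no CDS; empty protein set")
      return(Biostrings::AAStringSet())
    }
    out <- Biostrings::AAStringSet(fs$protein_seq)
  } else {
    if (!nrow(fs)) return(Biostrings::DNAStringSet())
    out <- Biostrings::DNAStringSet(fs$nucleotide_seq)
  }
  names(out) <- fs$locus_tag
  out
}

#' Summary statistics of a genome
#'
#' GC percent is computed over unambiguous bases only (`N` is excluded from
#' numerator and denominator); coding density counts each base pair once even
#' when CDS overlap, via interval union.
#'
#' @param genome A `genome_record`.
#' @return A one-row data frame: `genome_id`, `total_length`, `gc_percent`,
#'   `n_contigs`, `n_cds`, `coding_density`.
#' @export
genome_summary <- function(genome) {
  seqs <- toupper(vapply(genome$contigs, `[[`, "", "sequence"))
  total <- sum(nchar(seqs))
  if (total == 0L) stop("genome ", genome$genome_id, " has zero length")
  counts <- colSums(do.call(rbind, lapply(seqs, function(s) {
    tab <- table(strsplit(s, "")[[1]])
    vapply(c("A", "C", "G", "T"), function(b)
      if (b %in% names(tab)) as.integer(tab[[b]]) else 0L, 0L)
  })))
  acgt <- sum(counts)
  gc <- if (acgt > 0) 100 * (counts[["G"]] + counts[["C"]]) / acgt else NA_real_

  cds <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  covered <- 0L
  if (nrow(cds)) {
    for (acc in unique(cds$contig)) {
      sel <- cds[cds$contig == acc, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(start = sel$start + 1L, end = sel$end))
      covered <- covered + sum(IRanges::width(ir))
    }
  }
  data.frame(genome_id = genome$genome_id, total_length = total,
             gc_percent = gc, n_contigs = length(genome$contigs),
             n_cds = nrow(cds), coding_density = covered / total,
             stringsAsFactors = FALSE)
}

#' Tabulate summaries for several genomes
#'
#' @param genomes List of `genome_record` objects.
#' @return Data frame with one row per genome, as [genome_summary()].
#' @export
genome_summary_table <- function(genomes) {
  do.call(rbind, lapply(genomes, genome_summary))
}
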