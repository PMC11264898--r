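#' Extract the genomic region around a gene
#'
#' The window spans from `window_bp` upstream of the anchor's start to
#' `window_bp` downstream of its end, clipped to the contig bounds (no
#' wrap-around). All features overlapping the window are returned in start
#' order.
#'
#' @param genome A `genome_record`.
#' @param locus Anchor locus tag.
#' @param window_bp Flank size in bp on each side (default 8000, a typical
#'   operon scale).
#' @return A `region_view`: list with `genome_id`, `contig`, `window`
#'   (`c(start, end)`, 0-based half-open), `anchor`, `flipped` (FALSE here)
#'   and `features` (data frame slice of the genome's features, plus display
#'   coordinates `disp_start`, `disp_end`, `disp_strand` equal to the
#'   genomic ones).
#' @export
extract_region <- function(genome, locus, window_bp = 8000) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  fs <- genome$features
  hit <- which(fs$locus_tag == locus)
  if (!length(hit)) stop("unknown locus tag: ", locus)
  anchor <- fs[hit[1], ]
  clen <- genome$contigs[[anchor$contig]]$length
  win <- c(max(0L, anchor$start - as.integer(window_bp)),
           min(clen, anchor$end + as.integer(window_bp)))
  sel <- fs$contig == anchor$contig & fs$start < win[2] & fs$end > win[1]
  feats <- fs[sel, , drop = FALSE]
  feats <- feats[order(feats$start), , drop = FALSE]
  feats$disp_start <- feats$start
  feats$disp_end <- feats$end
  feats$disp_strand <- feats$strand
  rownames(feats) <- NULL
  structure(list(genome_id = genome$genome_id, contig = anchor$contig,
                 window = win, anchor = locus, flipped = FALSE,
                 features = feats),
            class = "region_view")
}

flip_region <- function(view) {
  win <- view$window
  f <- view$features
  ns <- win[1] + (win[2] - f$disp_end)
  ne <- win[1] + (win[2] - f$disp_start)
  f$disp_start <- ns
  f$disp_end <- ne
  f$disp_strand <- -f$disp_strand
  f <- f[order(f$disp_start), , drop = FALSE]
  rownames(f) <- NULL
  view$features <- f
  view$flipped <- !view$flipped
  view
}

#' Compare the genomic neighborhoods of a gene across genomes
#'
#' Builds one track per genome carrying an ortholog of the anchor gene (the
#' anchor's own genome first, then `target_genomes` in the given order; a
#' genome with several orthologs contributes the first by coordinate). Tracks
#' whose anchor ortholog lies on the opposite strand from the reference
#' anchor are flipped, mirroring display coordinates within the window, so
#' homologous regions read in the same direction. Links join features of
#' consecutive tracks that share an orthogroup and carry their amino-acid
#' percent identity. Genomes lacking an ortholog are skipped and listed in
#' `notices`.
#'
#' @param genomes Named list of `genome_record`s (names = genome ids).
#' @param anchor Locus tag of the gene of interest.
#' @param target_genomes Genome ids to compare against, in display order.
#' @param ogset An `orthogroup_set`; the anchor must be assigned.
#' @param window_bp Flank size in bp (default 8000).
#' @return A `region_comparison`: list with `tracks` (list of `region_view`),
#'   `links` (data frame `track_a`, `locus_a`, `track_b`, `locus_b`,
#'   `identity`) and `notices` (character).
#' @export
compare_regions <- function(genomes, anchor, target_genomes, ogset,
                            window_bp = 8000) {
  og_of <- og_index(ogset)
  og <- og_of[[anchor]]
  if (is.null(og)) stop("anchor ", anchor, " is not assigned to an orthogroup")
  members <- ogset$groups[[og]]

  anchor_genome <- NULL
  for (g in genomes) if (anchor %in% g$features$locus_tag) anchor_genome <- g
  if (is.null(anchor_genome)) stop("anchor ", anchor, " not found in any genome")

  ref <- extract_region(anchor_genome, anchor, window_bp)
  ref_strand <- ref$features$strand[ref$features$locus_tag == anchor]
  tracks <- list(ref)
  notices <- character(0)
  for (gid in setdiff(target_genomes, anchor_genome$genome_id)) {
    mine <- members[members$genome_id == gid, , drop = FALSE]
    if (!nrow(mine)) {
      notices <- c(notices, sprintf("genome %s has no ortholog of %s", gid, anchor))
      next
    }
    g <- genomes[[gid]]
    fs <- g$features
    cand <- fs[fs$locus_tag %in% mine$locus_tag, , drop = FALSE]
    cand <- cand[order(match(cand$contig, names(g$contigs)), cand$start), , drop = FALSE]
    ortho <- cand$locus_tag[1]
    view <- extract_region(g, ortho, window_bp)
    ostrand <- view$features$strand[view$features$locus_tag == ortho]
    if (ostrand != ref_strand) view <- flip_region(view)
    tracks[[length(tracks) + 1L]] <- view
  }

  links <- list()
  if (length(tracks) >= 2) for (t in seq_len(length(tracks) - 1L)) {
    a <- tracks[[t]]; b <- tracks[[t + 1L]]
    for (i in seq_len(nrow(a$features))) {
      la <- a$features$locus_tag[i]
      oga <- og_of[[la]]
      if (is.null(oga)) next
      match_b <- b$features[vapply(b$features$locus_tag, function(lb)
        identical(og_of[[lb]], oga), TRUE), , drop = FALSE]
      for (j in seq_len(nrow(match_b))) {
        pa <- a$features$protein_seq[i]
        pb <- match_b$protein_seq[j]
        ident <- if (!is.na(pa) && !is.na(pb)) pairwise_identity(pa, pb)
                 else NA_real_
        links[[length(links) + 1L]] <- data.frame(
          track_a = t, locus_a = la, track_b = t + 1L,
          locus_b = match_b$locus_tag[j], identity = ident,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(tracks = tracks,
                 links = if (length(links)) do.call(rbind, links) else
                   data.frame(track_a = integer(), locus_a = character(),
                              track_b = integer(), locus_b = character(),
                              identity = numeric(), stringsAsFactors = FALSE),
                 notices = notices),
            class = "region_comparison")
}

og_index <- function(ogset) {
  idx <- list()
  for (og in names(ogset$groups))
    for (lt in ogset$groups[[og]]$locus_tag) idx[[lt]] <- og
  idx
}

#' Circos-style comparison tracks for a reference genome
#'
#' For every CDS of the reference genome, in genomic order: its GC percent
#' (inner ring); per comparison genome, the percent identity of the best
#' homolog found via shared orthogroup membership (NA when absent); the
#' strand ring assignment (forward/reverse); and the total number of
#' homologs across the comparison genomes (outer histogram). Contig
#' boundaries are reported as cumulative coordinates. Every ring indexes the
#' same ordered reference CDS list.
#'
#' @param reference A `genome_record`.
#' @param genomes Named list of `genome_record`s including the comparison
#'   genomes.
#' @param comparison Character vector of genome ids to compare against.
#' @param ogset An `orthogroup_set` covering reference and comparison
#'   genomes.
#' @return A `track_set`: list with `reference`, `orfs` (data frame
#'   `locus_tag`, `contig`, `start`, `end`, `strand`, `gc_percent`,
#'   `homolog_count`), `identity` (matrix ORF x comparison genome of best
#'   homolog identities), `contig_boundaries` (named cumulative end
#'   positions).
#' @export
circos_tracks <- function(reference, genomes, comparison, ogset) {
  if (!length(comparison)) stop("comparison genome list must not be empty")
  og_of <- og_index(ogset)
  fs <- reference$features
  fs <- fs[fs$kind == "CDS", , drop = FALSE]
  fs <- fs[order(match(fs$contig, names(reference$contigs)), fs$start), , drop = FALSE]

  gc <- vapply(fs$nucleotide_seq, function(nt) {
    b <- strsplit(toupper(nt), "")[[1]]
    acgt <- sum(b %in% c("A", "C", "G", "T"))
    if (acgt == 0) return(NA_real_)
    100 * sum(b %in% c("G", "C")) / acgt
  }, 0, USE.NAMES = FALSE)

  ident <- matrix(NA_real_, nrow = nrow(fs), ncol = length(comparison),
                  dimnames = list(fs$locus_tag, comparison))
  hcount <- integer(nrow(fs))
  prot_of <- protein_lookup(genomes)
  for (i in seq_len(nrow(fs))) {
    og <- og_of[[fs$locus_tag[i]]]
    if (is.null(og)) next
    mem <- ogset$groups[[og]]
    for (g in comparison) {
      mine <- mem$locus_tag[mem$genome_id == g]
      hcount[i] <- hcount[i] + length(mine)
      if (!length(mine) || is.na(fs$protein_seq[i])) next
      ids <- vapply(mine, function(lt) {
        p <- prot_of[[lt]]
        if (is.null(p)) NA_real_ else pairwise_identity(fs$protein_seq[i], p)
      }, 0)
      if (any(!is.na(ids))) ident[i, g] <- max(ids, na.rm = TRUE)
    }
  }

  lens <- vapply(reference$contigs, `[[`, 0, "length")
  structure(list(reference = reference$genome_id,
                 orfs = data.frame(locus_tag = fs$locus_tag, contig = fs$contig,
                                   start = fs$start, end = fs$end,
                                   strand = fs$strand, gc_percent = gc,
                                   homolog_count = hcount,
                                   stringsAsFactors = FALSE),
                 identity = ident,
                 contig_boundaries = cumsum(lens)),
            class = "track_set")
}

protein_lookup <- function(genomes) {
  idx <- list()
  for (g in genomes) {
    cds <- g$features[g$features$kind == "CDS" & !is.na(g$features$protein_seq), ,
                      drop = FALSE]
    for (i in seq_len(nrow(cds))) idx[[cds$locus_tag[i]]] <- cds$protein_seq[i]
  }
  idx
}

#' Serialize a region comparison or track set to JSON
#'
#' Plot-ready JSON for external renderers; identity values are emitted raw
#' (binning and color scales are a rendering concern).
#'
#' @param x A `region_comparison` or `track_set`.
#' @param path Optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
region_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "region_comparison")) {
    list(type = "region_comparison",
         tracks = lapply(x$tracks, function(tr)
           list(genome_id = tr$genome_id, contig = tr$contig,
                window = tr$window, anchor = tr$anchor, flipped = tr$flipped,
                features = tr$features[, c("locus_tag", "kind", "disp_start",
                                           "disp_end", "disp_strand",
                                           "gene_name", "product")])),
         links = x$links, notices = x$notices)
  } else if (inherits(x, "track_set")) {
    list(type = "track_set", reference = x$reference, orfs = x$orfs,
         identity = as.data.frame(x$identity),
         contig_boundaries = as.list(x$contig_boundaries))
  } else stop("unsupported object")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
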