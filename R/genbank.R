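#' Parse a GenBank flat file into a genome record
#'
#' Reads an annotated bacterial genome in GenBank flat-file format. Each
#' `LOCUS`..`//` record becomes one contig; CDS, rRNA and tRNA features are
#' collected as gene features. A CDS carrying a `/translation` qualifier keeps
#' it verbatim; a CDS lacking one is translated from its nucleotide span using
#' the record's `/transl_table` (bacterial table 11 by default). Features with
#' a `/pseudo` qualifier become pseudogenes and carry no protein.
#'
#' Coordinates are stored 0-based half-open internally; GenBank's 1-based
#' inclusive coordinates are converted at the parsing boundary
#' (`start = GenBank start - 1`). Compound (`join`) locations concatenate
#' exons in feature order and are flagged in the `compound` column.
#'
#' @param path Path to a GenBank flat file (one genome, possibly multi-record).
#' @param genome_id Short unique identifier for the genome; defaults to the
#'   file name without extension.
#' @param display_name Human-readable name; defaults to the first record's
#'   `DEFINITION` line, falling back to `genome_id`.
#' @return A `genome_record` object: a list with `genome_id`, `display_name`,
#'   `contigs` (named list of `accession`, `sequence`, `length`) and
#'   `features` (data frame with columns `locus_tag`, `contig`, `start`,
#'   `end`, `strand`, `kind`, `gene_name`, `product`, `protein_seq`,
#'   `nucleotide_seq`, `compound`).
#' @export
parse_genbank <- function(path, genome_id = NULL, display_name = NULL) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.(gbk|gbff|gb|genbank)$", "", basename(path))

  # split into records on terminator lines
  ends <- grep("^//\\s*$", lines)
  starts <- grep("^LOCUS", lines)
  if (!length(ends)) ends <- length(lines)
  recs <- mapply(function(s, e) lines[s:e], starts,
                 vapply(starts, function(s) min(ends[ends >= s]), 1L),
                 SIMPLIFY = FALSE)

  contigs <- list()
  feats <- list()
  definition <- NULL
  for (rec in recs) {
    parsed <- parse_genbank_record(rec, path)
    if (is.null(definition)) definition <- parsed$definition
    contigs[[parsed$accession]] <-
      list(accession = parsed$accession, sequence = parsed$sequence,
           length = nchar(parsed$sequence))
    if (nrow(parsed$features)) feats[[length(feats) + 1L]] <- parsed$features
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_feature_table()
  rownames(features) <- NULL
  if (is.null(display_name))
    display_name <- if (!is.null(definition) && nzchar(definition)) definition else genome_id

  validate_features(features, contigs, path)
  structure(list(genome_id = genome_id, display_name = display_name,
                 contigs = contigs, features = features),
            class = "genome_record")
}

empty_feature_table <- function() {
  data.frame(locus_tag = character(), contig = character(),
             start = integer(), end = integer(), strand = integer(),
             kind = character(), gene_name = character(), product = character(),
             protein_seq = character(), nucleotide_seq = character(),
             compound = logical(), stringsAsFactors = FALSE)
}

validate_features <- function(features, contigs, path) {
  if (!nrow(features)) return(invisible(NULL))
  clen <- vapply(contigs, `[[`, 0, "length")
  bad <- features$start < 0L | features$end > clen[features$contig] |
    features$start >= features$end
  if (any(bad))
    stop("features with coordinates outside their contig in ", path, ": ",
         paste(features$locus_tag[bad], collapse = ", "))
}

# one LOCUS..// record -> accession, sequence, definition, feature table
parse_genbank_record <- function(lines, path) {
  locus <- strsplit(sub("^LOCUS\\s+", "", lines[1]), "\\s+")[[1]]
  accession <- locus[1]
  def_i <- grep("^DEFINITION", lines)
  definition <- if (length(def_i))
    trimws(sub("^DEFINITION\\s*", "", lines[def_i[1]])) else ""

  ori <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(ori)) {
    body <- lines[(ori[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (!nzchar(seq)) stop("record ", accession, " in ", path, " has no sequence")

  fstart <- grep("^FEATURES", lines)
  features <- empty_feature_table()
  if (length(fstart)) {
    fend <- if (length(ori)) ori[1] - 1L else length(lines)
    flines <- lines[(fstart[1] + 1L):fend]
    features <- parse_feature_block(flines, accession, seq)
  }
  list(accession = accession, sequence = seq, definition = definition,
       features = features)
}

parse_feature_block <- function(flines, accession, contig_seq) {
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  rows <- list()
  n_anon <- 0L
  for (i in seq_along(idx)) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^\\s+", "", substr(block[1], 1, 20))
    key <- strsplit(key, "\\s+")[[1]][1]
    if (key %in% c("source")) next

    # location may continue over lines until the first qualifier
    qual_i <- grep("^\\s{21}/", block)
    loc_end <- if (length(qual_i)) qual_i[1] - 1L else length(block)
    loc <- paste(gsub("\\s", "", c(substr(block[1], 22, nchar(block[1])),
                                   if (loc_end >= 2) trimws(block[2:loc_end]))),
                 collapse = "")
    quals <- parse_qualifiers(block[seq_len(length(block)) >= min(c(qual_i, Inf))])

    pseudo <- "pseudo" %in% names(quals) || "pseudogene" %in% names(quals)
    if (!(key %in% c("CDS", "rRNA", "tRNA", "tmRNA", "ncRNA")) &&
        !(key == "gene" && pseudo)) next

    locpar <- parse_location(loc)
    kind <- if (pseudo) "pseudogene"
            else if (key == "CDS") "CDS"
            else if (key %in% c("rRNA", "tRNA")) key else "other"

    nt <- extract_span(contig_seq, locpar)
    ltag <- quals[["locus_tag"]]
    if (is.null(ltag)) {
      n_anon <- n_anon + 1L
      ltag <- sprintf("%s_anon%04d", accession, n_anon)
    }
    protein <- NA_character_
    if (kind == "CDS") {
      protein <- quals[["translation"]]
      if (is.null(protein)) {
        table_id <- quals[["transl_table"]]
        protein <- translate_cds(nt, if (is.null(table_id)) "11" else table_id)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus_tag = ltag, contig = accession,
      start = locpar$start, end = locpar$end, strand = locpar$strand,
      kind = kind,
      gene_name = qual_or_na(quals, "gene"),
      product = qual_or_na(quals, "product"),
      protein_seq = if (is.null(protein)) NA_character_ else protein,
      nucleotide_seq = nt, compound = locpar$compound,
      stringsAsFactors = FALSE)
  }
  # drop pseudo 'gene' rows duplicating a parsed feature at the same tag
  tab <- if (length(rows)) do.call(rbind, rows) else empty_feature_table()
  tab[!duplicated(tab$locus_tag), , drop = FALSE]
}

qual_or_na <- function(quals, key) {
  v <- quals[[key]]
  if (is.null(v)) NA_character_ else v
}

parse_qualifiers <- function(lines) {
  if (!length(lines) || !any(grepl("^\\s{21}/", lines))) return(list())
  txt <- trimws(lines)
  starts <- grepl("^/", txt)
  # glue continuation lines (e.g. wrapped translations) to their qualifier
  grp <- cumsum(starts)
  keep <- grp > 0
  pieces <- vapply(split(txt[keep], grp[keep]), function(x) {
    joined <- character(0)
    for (p in x) {
      # translations wrap with no spaces; products wrap with a space
      joined <- c(joined, p)
    }
    paste(joined, collapse = "\n")
  }, "")
  quals <- list()
  for (p in pieces) {
    m <- regmatches(p, regexec('^/([A-Za-z_0-9]+)(=(.*))?$',
                               gsub("\n", "\x01", p)))[[1]]
    if (!length(m)) next
    key <- m[2]
    val <- if (nzchar(m[3])) gsub("\x01", "\n", m[4]) else TRUE
    if (is.character(val)) {
      val <- gsub('^"|"$', "", val)
      # translation continuation lines concatenate without separator,
      # free-text ones with a single space
      val <- if (key == "translation") gsub("\n", "", val)
             else gsub("\n", " ", val)
    }
    quals[[key]] <- val
  }
  quals
}

# GenBank location string -> start (0-based), end, strand, compound, exons
parse_location <- function(loc) {
  strand <- 1L
  s <- loc
  if (grepl("^complement\\(", s)) {
    strand <- -1L
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  compound <- FALSE
  if (grepl("^(join|order)\\(", s)) {
    compound <- TRUE
    s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  }
  parts <- strsplit(s, ",")[[1]]
  exons <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("complement", p)) {  # per-exon complement: treat whole as minus
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else {
      ab <- c(as.integer(p), as.integer(p))
    }
    ab
  }, integer(2)))
  if (any(is.na(exons))) stop("cannot parse location: ", loc)
  list(start = min(exons[, 1]) - 1L, end = max(exons[, 2]), strand = strand,
       compound = compound,
       exons = cbind(start = exons[, 1] - 1L, end = exons[, 2]))
}

# nucleotide span of a feature, exons concatenated, revcomp on minus strand
extract_span <- function(contig_seq, locpar) {
  ex <- locpar$exons
  pieces <- vapply(seq_len(nrow(ex)), function(i)
    substr(contig_seq, ex[i, 1] + 1L, ex[i, 2]), "")
  nt <- paste(pieces, collapse = "")
  if (locpar$strand < 0L)
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  nt
}

# translate a CDS span with the given NCBI genetic code; trailing stop removed
translate_cds <- function(nt, table_id = "11") {
  n <- nchar(nt)
  n <- n - n %% 3L
  if (n < 3L) return("")
  code <- Biostrings::getGeneticCode(as.character(table_id))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n)),
    genetic.code = code, if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Write a genome record as a GenBank flat file
#'
#' Serializes a `genome_record` back to GenBank flat format, one record per
#' contig. Internal 0-based half-open coordinates are converted back to
#' GenBank's 1-based inclusive convention. Used by the fixture generator and
#' for round-trip checks.
#'
#' @param genome A `genome_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in genome$contigs) {
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2000",
                       ct$accession, ct$length), con)
    writeLines(sprintf("DEFINITION  %s.", genome$display_name), con)
    writeLines(sprintf("ACCESSION   %s", ct$accession), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", ct$length), con)
    writeLines(sprintf('                     /organism="%s"', genome$display_name), con)
    fs <- genome$features[genome$features$contig == ct$accession, , drop = FALSE]
    if (nrow(fs)) fs <- fs[order(fs$start), , drop = FALSE]
    for (i in seq_len(nrow(fs))) {
      f <- fs[i, ]
      loc <- sprintf("%d..%d", f$start + 1L, f$end)
      if (f$strand < 0L) loc <- sprintf("complement(%s)", loc)
      key <- if (f$kind == "pseudogene") "CDS" else
             if (f$kind %in% c("rRNA", "tRNA")) f$kind else "CDS"
      writeLines(sprintf("     %-16s%s", key, loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', f$locus_tag), con)
      if (!is.na(f$gene_name))
        writeLines(sprintf('                     /gene="%s"', f$gene_name), con)
      if (!is.na(f$product))
        writeLines(wrap_qualifier("product", f$product), con)
      if (f$kind == "pseudogene") writeLines("                     /pseudo", con)
      if (f$kind == "CDS" && !is.na(f$protein_seq)) {
        writeLines("                     /transl_table=11", con)
        writeLines(wrap_qualifier("translation", f$protein_seq), con)
      }
    }
    writeLines("ORIGIN", con)
    seq <- ct$sequence
    pos <- seq(1L, nchar(seq), by = 60L)
    for (p in pos) {
      chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(key, value) {
  full <- sprintf('/%s="%s"', key, value)
  out <- character(0)
  width <- 58L
  first <- TRUE
  while (nchar(full) > 0) {
    take <- substr(full, 1, width)
    full <- substr(full, width + 1L, nchar(full))
    out <- c(out, paste0(strrep(" ", 21), take))
    first <- FALSE
  }
  out
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s)\n", x$genome_id, x$display_name))
  cat(sprintf("  contigs: %d  total: %d bp  features: %d (%d CDS)\n",
              length(x$contigs),
              sum(vapply(x$contigs, `[[`, 0, "length")),
              nrow(x$features), sum(x$features$kind == "CDS")))
  invisible(x)
}
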