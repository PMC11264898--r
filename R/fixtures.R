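#' Configuration for the synthetic genome generator
#'
#' Bundles and validates the parameters of [generate_fixture()]. Defaults
#' describe a small data set of closely related bacterial genomes: 6 genomes,
#' 20 gene families, 5% per-genome amino-acid divergence from the ancestral
#' sequence, 10% gene loss, no paralogs or pseudogenes, 3 metabolic modules,
#' and 15% of genes in annotated families lacking their own direct KO
#' annotation (the planted propagation cases).
#'
#' @param n_genomes Number of genomes.
#' @param n_families Number of ancestral gene families.
#' @param divergence Per-residue substitution probability per genome, in
#'   \[0, 1\].
#' @param paralog_rate Probability that a genome carries a duplicated copy of
#'   a family, in \[0, 1\].
#' @param loss_rate Probability that a genome lost a family, in \[0, 1\].
#' @param pseudogene_rate Probability that a retained gene is pseudogenized,
#'   in \[0, 1\].
#' @param n_modules Number of planted KEGG-style module definitions.
#' @param ko_missing_rate Probability that a gene of a KO-annotated family
#'   lacks its direct annotation, in \[0, 1\].
#' @param seed Mandatory integer seed; the whole fixture is a deterministic
#'   function of the configuration.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_genomes = 6, n_families = 20, divergence = 0.05,
                           paralog_rate = 0, loss_rate = 0.1,
                           pseudogene_rate = 0, n_modules = 3,
                           ko_missing_rate = 0.15, seed) {
  if (missing(seed)) stop("seed is mandatory")
  rates <- c(divergence = divergence, paralog_rate = paralog_rate,
             loss_rate = loss_rate, pseudogene_rate = pseudogene_rate,
             ko_missing_rate = ko_missing_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0,1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  structure(list(n_genomes = n_genomes, n_families = n_families,
                 divergence = divergence, paralog_rate = paralog_rate,
                 loss_rate = loss_rate, pseudogene_rate = pseudogene_rate,
                 n_modules = n_modules, ko_missing_rate = ko_missing_rate,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one fixed codon per amino acid; deterministic back-translation
aa_codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# substitution partners with positive BLOSUM62 score, to keep families alignable
blosum_partners <- function() {
  b <- get_blosum62()[aa_alphabet, aa_alphabet]
  lapply(stats::setNames(aa_alphabet, aa_alphabet), function(a) {
    p <- aa_alphabet[b[a, ] > 0 & aa_alphabet != a]
    if (!length(p)) aa_alphabet[aa_alphabet != a] else p
  })
}

#' Generate a synthetic annotated genome data set with known truth
#'
#' Simulates a set of bacterial genomes from ancestral gene families:
#' ancestral random proteins are evolved per genome by point substitutions
#' (drawn among BLOSUM62-favored exchanges), families are lost, duplicated
#' or pseudogenized at the configured rates, genes are back-translated with a
#' fixed codon table and laid out on one contig per genome with 100 bp
#' fixed-composition spacers, and valid GenBank flat files are emitted. The
#' companion truth tables record the planted orthogroup partition, KO/COG
#' annotations, planted propagation cases, module definitions and the
#' expected per-genome module completeness (computed by a self-contained
#' string-rewriting evaluator, independent of [module_completeness()]).
#'
#' @param config A `fixture_config`.
#' @param out_dir Optional directory; when given, per-genome `.gbk` files and
#'   truth TSVs are written there.
#' @return List with `genomes` (named list of `genome_record`),
#'   `truth` (list: `orthogroups` data frame, `ko`, `cog`,
#'   `propagation_cases`, `modules` data frame, `completeness_direct` and
#'   `completeness_propagated` matrices, `presence` matrix) and `config`.
#' @export
generate_fixture <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  partners <- blosum_partners()

  gids <- sprintf("GEN%02d", seq_len(config$n_genomes))
  fams <- sprintf("FAM%03d", seq_len(config$n_families))

  anc <- lapply(fams, function(f) {
    len <- sample(60:120, 1)
    c("M", sample(aa_alphabet, len - 1, replace = TRUE))
  })
  names(anc) <- fams
  fam_strand <- sample(c(1L, -1L), config$n_families, replace = TRUE, prob = c(0.7, 0.3))

  # presence layout: which genome carries which family (plus paralogs)
  present <- matrix(stats::runif(config$n_families * config$n_genomes) >= config$loss_rate,
                    nrow = config$n_families, dimnames = list(fams, gids))
  for (f in seq_len(config$n_families))  # keep every family in >= 1 genome
    if (!any(present[f, ])) present[f, sample(config$n_genomes, 1)] <- TRUE
  extra <- matrix(stats::runif(config$n_families * config$n_genomes) < config$paralog_rate,
                  nrow = config$n_families, dimnames = list(fams, gids)) & present

  genomes <- list()
  og_rows <- list()
  spacer <- strrep("ACGT", 25)
  for (g in gids) {
    feats <- list()
    seq_parts <- spacer
    pos <- nchar(spacer)
    counter <- 0L
    for (fi in seq_len(config$n_families)) {
      if (!present[fi, g]) next
      ncopies <- 1L + as.integer(extra[fi, g])
      for (cp in seq_len(ncopies)) {
        counter <- counter + 1L
        tag <- sprintf("%s_%04d", g, counter)
        prot <- mutate_protein(anc[[fi]], config$divergence, partners)
        pseudo <- stats::runif(1) < config$pseudogene_rate
        nt_fwd <- paste0(paste(aa_codon[prot], collapse = ""), "TAA")
        strand <- fam_strand[fi]
        contig_piece <- if (strand > 0) nt_fwd else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt_fwd)))
        start <- pos
        end <- pos + nchar(nt_fwd)
        feats[[length(feats) + 1L]] <- data.frame(
          locus_tag = tag, contig = sprintf("%s_contig1", g),
          start = start, end = end, strand = strand,
          kind = if (pseudo) "pseudogene" else "CDS",
          gene_name = sprintf("fam%03d", fi),
          product = sprintf("family %03d protein", fi),
          protein_seq = if (pseudo) NA_character_ else paste(prot, collapse = ""),
          nucleotide_seq = nt_fwd, compound = FALSE,
          stringsAsFactors = FALSE)
        og_rows[[length(og_rows) + 1L]] <- data.frame(
          og_id = fams[fi], genome_id = g, locus_tag = tag, kind =
            if (pseudo) "pseudogene" else "CDS", stringsAsFactors = FALSE)
        seq_parts <- c(seq_parts, contig_piece, spacer)
        pos <- end + nchar(spacer)
      }
    }
    contig_seq <- paste(seq_parts, collapse = "")
    acc <- sprintf("%s_contig1", g)
    genomes[[g]] <- structure(
      list(genome_id = g, display_name = sprintf("Synthetic bacterium %s", g),
           contigs = stats::setNames(list(list(accession = acc,
                                               sequence = contig_seq,
                                               length = nchar(contig_seq))), acc),
           features = do.call(rbind, feats)),
      class = "genome_record")
  }
  og_table <- do.call(rbind, og_rows)

  # KO annotations: ~80% of families carry a KO; genes may lack the direct
  # annotation (the planted propagation cases)
  fam_ko <- stats::setNames(ifelse(stats::runif(config$n_families) < 0.8,
                                   sprintf("K%05d", seq_len(config$n_families)),
                                   NA_character_), fams)
  ko_rows <- list(); prop_rows <- list()
  cds <- og_table[og_table$kind == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    ko <- fam_ko[[cds$og_id[i]]]
    if (is.na(ko)) next
    if (stats::runif(1) < config$ko_missing_rate) {
      prop_rows[[length(prop_rows) + 1L]] <- data.frame(
        genome_id = cds$genome_id[i], locus_tag = cds$locus_tag[i], ko = ko,
        og_id = cds$og_id[i], stringsAsFactors = FALSE)
    } else {
      ko_rows[[length(ko_rows) + 1L]] <- data.frame(
        genome_id = cds$genome_id[i], locus_tag = cds$locus_tag[i], ko = ko,
        stringsAsFactors = FALSE)
    }
  }
  ko_tab <- if (length(ko_rows)) do.call(rbind, ko_rows) else
    data.frame(genome_id = character(), locus_tag = character(),
               ko = character(), stringsAsFactors = FALSE)
  ko_tab$provenance <- if (nrow(ko_tab)) "direct" else character(0)
  prop_tab <- if (length(prop_rows)) do.call(rbind, prop_rows) else
    data.frame(genome_id = character(), locus_tag = character(),
               ko = character(), og_id = character(), stringsAsFactors = FALSE)

  # COG-style categories, one per family
  cog_cats <- c("C", "E", "G", "J", "K", "L", "M", "O", "P", "T")
  fam_cog <- stats::setNames(sample(cog_cats, config$n_families, replace = TRUE), fams)
  cog_tab <- data.frame(genome_id = cds$genome_id, locus_tag = cds$locus_tag,
                        annotation_id = sprintf("COG%04d", match(cds$og_id, fams)),
                        category_code = fam_cog[cds$og_id],
                        category_label = paste("category", fam_cog[cds$og_id]),
                        stringsAsFactors = FALSE)

  modules <- plant_modules(config$n_modules, fam_ko)
  # expected completeness under direct and propagated KO sets
  direct_kos <- lapply(stats::setNames(gids, gids), function(g)
    unique(ko_tab$ko[ko_tab$genome_id == g]))
  prop_kos <- lapply(stats::setNames(gids, gids), function(g) {
    rows <- prop_tab[prop_tab$genome_id == g, , drop = FALSE]
    # a planted case only resolves if some orthogroup mate has the direct KO
    resolved <- vapply(seq_len(nrow(rows)), function(i) {
      mates <- og_table$locus_tag[og_table$og_id == rows$og_id[i]]
      any(ko_tab$ko == rows$ko[i] & ko_tab$locus_tag %in% mates)
    }, TRUE)
    unique(c(direct_kos[[g]], rows$ko[resolved]))
  })
  comp_direct <- comp_prop <- matrix(
    0, nrow = nrow(modules), ncol = length(gids),
    dimnames = list(modules$module_id, gids))
  for (m in seq_len(nrow(modules))) for (g in gids) {
    comp_direct[m, g] <- eval_definition_string(modules$definition[m], direct_kos[[g]])
    comp_prop[m, g] <- eval_definition_string(modules$definition[m], prop_kos[[g]])
  }

  presence <- t(vapply(fams, function(f) {
    vapply(gids, function(g)
      sum(og_table$og_id == f & og_table$genome_id == g), 0L)
  }, stats::setNames(integer(length(gids)), gids)))

  truth <- list(orthogroups = og_table, ko = ko_tab, cog = cog_tab,
                propagation_cases = prop_tab, modules = modules,
                completeness_direct = comp_direct,
                completeness_propagated = comp_prop,
                presence = presence, fam_ko = fam_ko)
  fx <- list(genomes = genomes, truth = truth, config = config)
  if (!is.null(out_dir)) write_fixture(fx, out_dir)
  fx
}

mutate_protein <- function(residues, divergence, partners) {
  if (divergence <= 0) return(residues)
  hit <- which(stats::runif(length(residues)) < divergence)
  hit <- hit[hit > 1]  # keep the initiator methionine
  for (i in hit) {
    p <- partners[[residues[i]]]
    residues[i] <- p[sample.int(length(p), 1)]
  }
  residues
}

# random but structured module definitions over the planted KO inventory
plant_modules <- function(n_modules, fam_ko) {
  kos <- fam_ko[!is.na(fam_ko)]
  if (length(kos) < 4) stop("too few annotated families to plant modules")
  defs <- character(n_modules)
  for (m in seq_len(n_modules)) {
    n_steps <- sample(2:4, 1)
    steps <- vapply(seq_len(n_steps), function(s) {
      pick <- sample(kos, min(length(kos), sample(1:3, 1)))
      kind <- sample(c("atom", "alt", "complex"), 1,
                     prob = c(0.5, 0.25, 0.25))
      if (kind == "atom" || length(pick) == 1) pick[1]
      else if (kind == "alt") paste0("(", paste(pick, collapse = ","), ")")
      else paste(pick, collapse = "+")
    }, "")
    defs[m] <- paste(steps, collapse = " ")
  }
  data.frame(module_id = sprintf("M%05d", seq_len(n_modules)),
             definition = defs, stringsAsFactors = FALSE)
}

# Self-contained evaluator of a definition string against a KO set, working
# by textual rewriting (innermost parentheses reduced to numeric literals).
# Intentionally independent of the parser/tree evaluator in kegg.R.
eval_definition_string <- function(def, ko_present) {
  s <- def
  locs <- gregexpr("[KM][0-9]{5}", s)[[1]]
  if (locs[1] != -1) {
    ids <- regmatches(s, gregexpr("[KM][0-9]{5}", s))[[1]]
    for (id in unique(ids))
      s <- gsub(id, if (id %in% ko_present) "1" else "0", s, fixed = TRUE)
  }
  s <- gsub("--", "1", s, fixed = TRUE)
  repeat {
    m <- regexpr("\\(([^()]*)\\)", s)
    if (m == -1) break
    inner <- sub("^\\(", "", sub("\\)$", "", regmatches(s, m)))
    v <- eval_flat_definition(inner)
    regmatches(s, m) <- format(v, digits = 15)
  }
  eval_flat_definition(s)
}

eval_flat_definition <- function(s) {
  steps <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  mean(vapply(steps, function(st) {
    alts <- strsplit(st, ",", fixed = TRUE)[[1]]
    max(vapply(alts, eval_flat_complex, 0))
  }, 0))
}

eval_flat_complex <- function(cx) {
  m <- gregexpr("([+-]?)([0-9.]+)", cx)[[1]]
  toks <- regmatches(cx, list(m))[[1]]
  signs <- sub("^([+-]?).*$", "\\1", toks)
  vals <- as.numeric(sub("^[+-]?", "", toks))
  if (length(vals) == 1 && signs[1] != "-") return(vals[1])
  req <- vals[signs != "-"]
  if (!length(req)) return(1)
  as.numeric(all(req == 1))
}

write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in fx$genomes)
    write_genbank(g, file.path(out_dir, paste0(g$genome_id, ".gbk")))
  tr <- fx$truth
  # orthogroup table in the standard tab-separated dialect
  gids <- names(fx$genomes)
  ogs <- unique(tr$orthogroups$og_id)
  tab <- data.frame(Orthogroup = ogs, stringsAsFactors = FALSE)
  for (g in gids)
    tab[[g]] <- vapply(ogs, function(og) paste(
      tr$orthogroups$locus_tag[tr$orthogroups$og_id == og &
                                 tr$orthogroups$genome_id == g],
      collapse = ", "), "")
  utils::write.table(tab, file.path(out_dir, "orthogroups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$ko[, c("genome_id", "locus_tag", "ko")],
                     file.path(out_dir, "ko.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(tr$cog, file.path(out_dir, "cog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(tr$modules, file.path(out_dir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(genome_summary_table(fx$genomes),
                     file.path(out_dir, "summaries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
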