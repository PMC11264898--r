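#' Parse a KEGG module definition string
#'
#' The KEGG module definition language describes a metabolic module as an
#' expression over KEGG orthologs (K numbers) and nested modules (M numbers):
#' a space separates consecutive steps (all required), a comma separates
#' interchangeable alternatives, `+` joins the subunits of a complex (all
#' required), a leading `-` inside a complex marks an optional subunit, `--`
#' is a placeholder for a reaction with no known ortholog, and parentheses
#' group. Operator binding from tightest to loosest: `+`/`-`, then `,`,
#' then space.
#'
#' @param text Definition string, e.g. `"(K00001,K00002) K00003+K00004"`.
#' @param module_id Optional module identifier (M number) carried in the
#'   result.
#' @return A `module_definition`: list with `module_id` and `expression`, the
#'   parsed tree of nodes `atom`, `steps`, `alt`, `complex`, `optional`,
#'   `gap`.
#' @export
parse_module_definition <- function(text, module_id = NA_character_) {
  if (!nzchar(trimws(text))) stop("empty module definition")
  toks <- kegg_tokenize(text)
  st <- new.env()
  st$toks <- toks
  st$i <- 1L
  expr <- kegg_parse_steps(st, text)
  if (st$i <= length(st$toks))
    kegg_parse_error(text, st$toks[[st$i]]$pos,
                     paste0("unexpected '", st$toks[[st$i]]$text, "'"))
  structure(list(module_id = module_id, expression = expr),
            class = "module_definition")
}

kegg_parse_error <- function(text, pos, why) {
  stop(sprintf("module definition parse error at position %d: %s (in \"%s\")",
               pos, why, text), call. = FALSE)
}

kegg_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^([KM][0-9]{5}|--|[+,()[:space:]-])", rest))
    if (!length(m)) kegg_parse_error(text, i, "illegal token")
    type <- if (grepl("^[KM]", m)) "id"
            else switch(m, "--" = "gap", "+" = "plus", "-" = "minus",
                        "," = "comma", "(" = "lp", ")" = "rp", "space")
    if (grepl("^[[:space:]]$", m)) type <- "space"
    # collapse runs of whitespace into one separator token
    if (type == "space" && length(toks) && toks[[length(toks)]]$type == "space") {
      i <- i + 1L
      next
    }
    toks[[length(toks) + 1L]] <- list(type = type, text = m, pos = i)
    i <- i + nchar(m)
  }
  # strip leading/trailing separators
  while (length(toks) && toks[[1]]$type == "space") toks <- toks[-1]
  while (length(toks) && toks[[length(toks)]]$type == "space")
    toks <- toks[-length(toks)]
  toks
}

kegg_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
kegg_next <- function(st) { t <- kegg_peek(st); st$i <- st$i + 1L; t }

# steps := alt (SPACE alt)*
kegg_parse_steps <- function(st, text) {
  children <- list(kegg_parse_alt(st, text))
  repeat {
    t <- kegg_peek(st)
    if (is.null(t) || t$type != "space") break
    kegg_next(st)
    children[[length(children) + 1L]] <- kegg_parse_alt(st, text)
  }
  if (length(children) == 1L) children[[1L]]
  else list(type = "steps", children = children)
}

# alt := complex (',' complex)*
kegg_parse_alt <- function(st, text) {
  children <- list(kegg_parse_complex(st, text))
  repeat {
    t <- kegg_peek(st)
    if (is.null(t) || t$type != "comma") break
    op <- kegg_next(st)
    nxt <- kegg_peek(st)
    if (is.null(nxt)) kegg_parse_error(text, op$pos, "dangling ','")
    children[[length(children) + 1L]] <- kegg_parse_complex(st, text)
  }
  if (length(children) == 1L) children[[1L]]
  else list(type = "alt", children = children)
}

# complex := ['-'] unit (('+'|'-') unit)* ; '-' marks the following unit optional
kegg_parse_complex <- function(st, text) {
  children <- list()
  t <- kegg_peek(st)
  lead_opt <- FALSE
  if (!is.null(t) && t$type == "minus") {
    lead_opt <- TRUE
    kegg_next(st)
  }
  first <- kegg_parse_unit(st, text)
  children[[1L]] <- if (lead_opt) list(type = "optional", child = first) else first
  repeat {
    t <- kegg_peek(st)
    if (is.null(t) || !(t$type %in% c("plus", "minus"))) break
    op <- kegg_next(st)
    nxt <- kegg_peek(st)
    if (is.null(nxt) || !(nxt$type %in% c("id", "gap", "lp")))
      kegg_parse_error(text, op$pos, paste0("dangling '", op$text, "'"))
    unit <- kegg_parse_unit(st, text)
    children[[length(children) + 1L]] <-
      if (op$type == "minus") list(type = "optional", child = unit) else unit
  }
  if (length(children) == 1L && !lead_opt) children[[1L]]
  else list(type = "complex", children = children)
}

# unit := ID | '--' | '(' steps ')'
kegg_parse_unit <- function(st, text) {
  t <- kegg_peek(st)
  if (is.null(t)) kegg_parse_error(text, nchar(text) + 1L, "unexpected end of definition")
  if (t$type == "id") { kegg_next(st); return(list(type = "atom", id = t$text)) }
  if (t$type == "gap") { kegg_next(st); return(list(type = "gap")) }
  if (t$type == "lp") {
    kegg_next(st)
    inner <- kegg_parse_steps(st, text)
    cl <- kegg_peek(st)
    if (is.null(cl) || cl$type != "rp")
      kegg_parse_error(text, t$pos, "unbalanced parenthesis")
    kegg_next(st)
    return(inner)
  }
  kegg_parse_error(text, t$pos, paste0("unexpected '", t$text, "'"))
}

#' Serialize a module definition tree back to definition-language text
#'
#' Inverse of [parse_module_definition()]: parsing the serialized text yields
#' an identical tree.
#'
#' @param definition A `module_definition` or a bare expression node.
#' @return Definition string.
#' @export
serialize_module_definition <- function(definition) {
  node <- if (inherits(definition, "module_definition")) definition$expression
          else definition
  kegg_serialize_node(node)
}

kegg_serialize_node <- function(node) {
  wrap_if <- function(child, types) {
    s <- kegg_serialize_node(child)
    if (child$type %in% types) paste0("(", s, ")") else s
  }
  switch(node$type,
    atom = node$id,
    gap = "--",
    steps = paste(vapply(node$children, function(ch)
      wrap_if(ch, "steps"), ""), collapse = " "),
    alt = paste(vapply(node$children, function(ch)
      wrap_if(ch, c("steps", "alt")), ""), collapse = ","),
    complex = paste0(vapply(seq_along(node$children), function(i) {
      ch <- node$children[[i]]
      opt <- identical(ch$type, "optional")
      inner <- if (opt) ch$child else ch
      s <- wrap_if(inner, c("steps", "alt", "complex"))
      if (opt) paste0("-", s)
      else if (i == 1L) s
      else paste0("+", s)
    }, ""), collapse = ""),
    optional = paste0("-", kegg_serialize_node(node$child)),
    stop("unknown node type: ", node$type))
}

kegg_atoms <- function(node) {
  switch(node$type,
    atom = node$id,
    gap = character(0),
    optional = kegg_atoms(node$child),
    unique(unlist(lapply(node$children, kegg_atoms))))
}

#' Completeness of a KEGG module given a set of present orthologs
#'
#' Evaluates the definition tree recursively: an atom scores 1 if its KO is
#' present, 0 otherwise; a `--` gap scores 1 (it denotes a reaction with no
#' known ortholog; set `gap_value = 0` to count gaps as missing); a complex
#' scores 1 only if every non-optional subunit scores 1; alternatives score
#' the maximum of their branches; a step sequence scores the arithmetic mean
#' of its steps, which yields the fractional module completeness. Nested
#' module atoms (M numbers) are resolved recursively when their definitions
#' are supplied, and otherwise count as unsatisfied with a warning.
#'
#' @param definition A `module_definition`.
#' @param ko_present Character vector of KO identifiers present in the
#'   genome.
#' @param definitions Optional named list of `module_definition` objects used
#'   to resolve nested M-number atoms.
#' @param gap_value Value of a `--` gap placeholder, 1 (default) or 0.
#' @return A `completeness_result`: list with `module_id`, `completeness`
#'   in \[0, 1\], `satisfied_atoms` (KOs of the definition found present) and
#'   `atoms` (all KO/M atoms of the definition).
#' @export
module_completeness <- function(definition, ko_present, definitions = NULL,
                                gap_value = 1) {
  stopifnot(inherits(definition, "module_definition"))
  atoms <- kegg_atoms(definition$expression)
  val <- kegg_eval(definition$expression, ko_present, definitions, gap_value,
                   visiting = character(0))
  structure(list(module_id = definition$module_id,
                 completeness = val,
                 satisfied_atoms = intersect(atoms, ko_present),
                 atoms = atoms),
            class = "completeness_result")
}

kegg_eval <- function(node, ko_present, definitions, gap_value, visiting) {
  switch(node$type,
    atom = {
      if (grepl("^M", node$id)) {
        if (node$id %in% visiting) return(0)
        def <- definitions[[node$id]]
        if (is.null(def)) {
          warning("nested module ", node$id,
                  " has no supplied definition; counted as unsatisfied")
          return(0)
        }
        v <- kegg_eval(def$expression, ko_present, definitions, gap_value,
                       c(visiting, node$id))
        return(as.numeric(v == 1))
      }
      as.numeric(node$id %in% ko_present)
    },
    gap = gap_value,
    optional = 1,  # optional parts never block; scored only inside complexes
    complex = {
      req <- Filter(function(ch) !identical(ch$type, "optional"), node$children)
      if (!length(req)) return(1)
      vals <- vapply(req, kegg_eval, 0, ko_present = ko_present,
                     definitions = definitions, gap_value = gap_value,
                     visiting = visiting)
      as.numeric(all(vals == 1))
    },
    alt = max(vapply(node$children, kegg_eval, 0, ko_present = ko_present,
                     definitions = definitions, gap_value = gap_value,
                     visiting = visiting)),
    steps = mean(vapply(node$children, kegg_eval, 0, ko_present = ko_present,
                        definitions = definitions, gap_value = gap_value,
                        visiting = visiting)),
    stop("unknown node type: ", node$type))
}

#' Propagate KO annotations within orthogroups
#'
#' A gene lacking a direct annotation for KO k gains k (with provenance
#' "propagated" and the orthogroup recorded as source) whenever at least one
#' member of its orthogroup is directly annotated with k. Direct entries are
#' never modified; propagated entries are recomputed from the direct entries
#' alone, so the operation is idempotent.
#'
#' @param assignments Data frame with columns `genome_id`, `locus_tag`, `ko`
#'   and optionally `provenance` (missing provenance is taken as "direct").
#' @param ogset An `orthogroup_set`.
#' @param genomes Optional list of `genome_record`s; when given, every
#'   assignment must reference an existing gene.
#' @return Data frame with columns `genome_id`, `locus_tag`, `ko`,
#'   `provenance`, `source_og` (NA for direct entries).
#' @export
propagate_annotations <- function(assignments, ogset, genomes = NULL) {
  if (!all(c("genome_id", "locus_tag", "ko") %in% colnames(assignments)))
    stop("assignments need columns genome_id, locus_tag, ko")
  if (is.null(assignments$provenance)) assignments$provenance <- "direct"
  if (!is.null(genomes)) {
    known <- gene_universe(genomes)$locus_tag
    bad <- setdiff(assignments$locus_tag, known)
    if (length(bad))
      stop("assignment references unknown gene(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  direct <- assignments[assignments$provenance == "direct", , drop = FALSE]
  direct$source_og <- NA_character_

  prop <- list()
  for (og in names(ogset$groups)) {
    mem <- ogset$groups[[og]]
    dmem <- direct[direct$locus_tag %in% mem$locus_tag, , drop = FALSE]
    if (!nrow(dmem)) next
    for (ko in unique(dmem$ko)) {
      has <- dmem$locus_tag[dmem$ko == ko]
      lacking <- mem[!(mem$locus_tag %in% has), , drop = FALSE]
      if (nrow(lacking))
        prop[[length(prop) + 1L]] <- data.frame(
          genome_id = lacking$genome_id, locus_tag = lacking$locus_tag,
          ko = ko, provenance = "propagated", source_og = og,
          stringsAsFactors = FALSE)
    }
  }
  out <- rbind(direct[, c("genome_id", "locus_tag", "ko", "provenance", "source_og")],
               if (length(prop)) do.call(rbind, prop))
  out <- out[!duplicated(out[, c("genome_id", "locus_tag", "ko", "provenance")]), ,
             drop = FALSE]
  out <- out[order(out$genome_id, out$locus_tag, out$ko, out$provenance), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Module-by-genome completeness matrix
#'
#' Evaluates each module definition against each genome's set of present
#' KOs (direct annotations, plus orthogroup-propagated ones when
#' `use_propagated`). Alongside the completeness values, per-module KO gene
#' counts are returned: for every KO atom of a module, the number of genes of
#' the genome annotated with it (the per-square counts of module-detail
#' heatmaps).
#'
#' @param definitions Named list of `module_definition` objects (names =
#'   module ids), e.g. from [read_module_definitions()].
#' @param assignments KO assignment data frame as accepted/produced by
#'   [propagate_annotations()].
#' @param genome_ids Character vector of genome ids (matrix columns).
#' @param use_propagated Include entries with provenance "propagated"
#'   (default TRUE).
#' @param gap_value Passed to [module_completeness()].
#' @return A `completeness_matrix` object: list with `completeness` (numeric
#'   module x genome matrix), `results` (nested list of
#'   `completeness_result`), `ko_counts` (per module, an atom x genome count
#'   matrix) and `use_propagated`.
#' @export
completeness_matrix <- function(definitions, assignments, genome_ids,
                                use_propagated = TRUE, gap_value = 1) {
  if (is.null(assignments$provenance)) assignments$provenance <- "direct"
  use <- assignments[use_propagated | assignments$provenance == "direct", ,
                     drop = FALSE]
  mods <- names(definitions)
  comp <- matrix(0, nrow = length(mods), ncol = length(genome_ids),
                 dimnames = list(mods, genome_ids))
  results <- stats::setNames(vector("list", length(mods)), mods)
  ko_counts <- stats::setNames(vector("list", length(mods)), mods)
  for (m in mods) {
    atoms <- kegg_atoms(definitions[[m]]$expression)
    cnt <- matrix(0L, nrow = length(atoms), ncol = length(genome_ids),
                  dimnames = list(atoms, genome_ids))
    results[[m]] <- stats::setNames(vector("list", length(genome_ids)), genome_ids)
    for (g in genome_ids) {
      sel <- use[use$genome_id == g, , drop = FALSE]
      kos <- unique(sel$ko)
      res <- module_completeness(definitions[[m]], kos,
                                 definitions = definitions,
                                 gap_value = gap_value)
      res$used_propagated <- any(sel$provenance[sel$ko %in% res$satisfied_atoms]
                                 == "propagated")
      comp[m, g] <- res$completeness
      results[[m]][[g]] <- res
      for (a in atoms)
        cnt[a, g] <- length(unique(sel$locus_tag[sel$ko == a]))
    }
    ko_counts[[m]] <- cnt
  }
  structure(list(completeness = comp, results = results,
                 ko_counts = ko_counts, use_propagated = use_propagated),
            class = "completeness_matrix")
}

#' Read module definitions from a two-column TSV
#'
#' @param path TSV with columns `module_id` and `definition` (no header
#'   required; a header row is auto-detected).
#' @return Named list of `module_definition` objects.
#' @export
read_module_definitions <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("module_id", "definition"))
  if (nrow(tab) && tab$module_id[1] == "module_id") tab <- tab[-1, , drop = FALSE]
  defs <- lapply(seq_len(nrow(tab)), function(i)
    parse_module_definition(tab$definition[i], module_id = tab$module_id[i]))
  stats::setNames(defs, tab$module_id)
}

#' Read KO assignments from a TSV
#'
#' @param path TSV with columns `genome_id`, `locus_tag`, `ko` (header
#'   auto-detected).
#' @return Data frame with those columns and `provenance = "direct"`.
#' @export
read_ko_assignments <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("genome_id", "locus_tag", "ko"))
  if (nrow(tab) && tab$genome_id[1] == "genome_id") tab <- tab[-1, , drop = FALSE]
  tab$provenance <- "direct"
  rownames(tab) <- NULL
  tab
}
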